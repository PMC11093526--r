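test_that("assemble_V matches closed forms and flags non-PD points", {
  n <- 12
  ids <- sprintf("i%d", seq_len(n))
  Gid <- grmatrix(diag(n), ids = ids, m_used = 1, label = "gI")
  y <- stats::setNames(stats::rnorm(n), ids)
  m <- mixed_model(y, list(Gid))
  h <- assemble_V(m, c(1, 1))
  expect_equal(h$logdet_V, n * log(2), tolerance = 1e-12)
  expect_s3_class(h, "vc_chol")

  expect_error(assemble_V(m, c(-2, 1)), class = "vcpart_not_pd")

  ## random PSD component: log|V| against the eigenvalue oracle
  d <- toy_dataset(n = 30, K = 1, seed = 14)
  mm <- mixed_model(d$y, d$grms)
  hh <- assemble_V(mm, c(0.7, 0.5))
  V <- dense_V(mm, c(0.7, 0.5))
  expect_equal(hh$logdet_V, sum(log(eigen(V, symmetric = TRUE)$values)),
               tolerance = 1e-8)
})

test_that("projection_apply annihilates fixed effects and matches dense P", {
  set.seed(15)
  X <- cbind(stats::rnorm(25), stats::rnorm(25))
  m <- toy_model(n = 25, K = 1, m_per = 30, seed = 15, X = X)
  vc <- c(0.8, 0.6)
  h <- assemble_V(m, vc)
  w <- stats::rnorm(25)

  Pw <- projection_apply(m, h, w)
  expect_equal(unname(drop(crossprod(m$X, Pw))), rep(0, 3), tolerance = 1e-8)
  cc <- stats::rnorm(3)
  expect_lt(max(abs(projection_apply(m, h, drop(m$X %*% cc)))),
            1e-8 * max(abs(cc)))
  expect_equal(Pw, drop(dense_P(m, vc) %*% w), tolerance = 1e-8)

  ## intercept-only with V = I is just centering
  n <- 10; ids <- sprintf("i%d", 1:n)
  mi <- mixed_model(stats::setNames(stats::rnorm(n), ids),
                    list(grmatrix(diag(n), ids, 1, "gI")))
  hi <- assemble_V(mi, c(0, 1))
  wi <- stats::rnorm(n)
  expect_equal(projection_apply(mi, hi, wi), wi - mean(wi), tolerance = 1e-10)
})

test_that("restricted likelihood matches the dense oracle and is invariant to X reparameterization", {
  set.seed(16)
  X <- cbind(stats::rnorm(20))
  m <- toy_model(n = 20, K = 1, m_per = 25, seed = 16, X = X)
  vc <- c(1.2, 0.7)
  expect_equal(reml_loglik(m, vc), dense_reml_loglik(m, vc), tolerance = 1e-8)

  A <- matrix(c(2, 1, 0.5, -1), 2, 2)    # invertible reparameterization
  m2 <- m
  m2$X <- m$X %*% A
  expect_equal(reml_loglik(m2, vc), reml_loglik(m, vc), tolerance = 1e-8)
})

test_that("likelihood is invariant to consistent individual reordering", {
  d <- toy_dataset(n = 40, K = 2, m_per = 30, seed = 17)
  m1 <- mixed_model(d$y, d$grms)
  perm <- sample(seq_along(d$y))
  m2 <- mixed_model(d$y[perm], d$grms)   # GRMs realigned by id
  vc <- c(0.5, 0.9, 1.1)
  expect_equal(reml_loglik(m2, vc), reml_loglik(m1, vc), tolerance = 1e-10)
})

test_that("exact gradient agrees with finite differences of the likelihood", {
  m <- toy_model(n = 30, K = 2, m_per = 25, seed = 18)
  vc <- c(0.9, 1.1, 1.3)
  g <- gradient_exact(m, vc)
  step <- 1e-5
  for (k in seq_along(vc)) {
    e <- numeric(length(vc)); e[k] <- step
    fd <- (reml_loglik(m, vc + e) - reml_loglik(m, vc - e)) / (2 * step)
    expect_equal(g[k], fd, tolerance = 1e-4)
  }
})

test_that("duplicated components produce symmetric gradients and a singular Fisher matrix", {
  d <- toy_dataset(n = 25, K = 1, m_per = 30, seed = 19)
  m <- mixed_model(d$y, list(d$grms[[1]], d$grms[[1]]))
  vc <- c(0.5, 0.5, 1)
  g <- gradient_exact(m, vc)
  expect_equal(g[1], g[2], tolerance = 1e-10)
  Fm <- fisher_info_exact(m, vc)
  expect_equal(Fm[1, ], Fm[2, ], tolerance = 1e-10)
})

test_that("exact Fisher information matches the dense 1/2 tr(PG_k P G_l) oracle and is PSD", {
  set.seed(20)
  X <- cbind(stats::rnorm(20))
  m <- toy_model(n = 20, K = 2, m_per = 20, seed = 20, X = X)
  vc <- c(0.8, 1.2, 0.9)
  Fm <- fisher_info_exact(m, vc)
  P <- dense_P(m, vc)
  mats <- list(matrix(m$Gstack[, 1], 20, 20), matrix(m$Gstack[, 2], 20, 20),
               diag(m$R_diag))
  for (k in 1:3)
    for (l in 1:3)
      expect_equal(Fm[k, l],
                   0.5 * sum(diag(P %*% mats[[k]] %*% P %*% mats[[l]])),
                   tolerance = 1e-8)
  expect_gt(min(eigen(Fm, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("P V P = P holds through the factorized solves", {
  m <- toy_model(n = 30, K = 2, m_per = 25, seed = 22)
  vc <- c(0.7, 1.0, 0.8)
  h <- assemble_V(m, vc)
  V <- dense_V(m, vc)
  for (rep in 1:5) {
    w <- stats::rnorm(30)
    Pw <- projection_apply(m, h, w)
    expect_equal(projection_apply(m, h, drop(V %*% Pw)), Pw,
                 tolerance = 1e-8)
  }
})

test_that("stochastic gradient and Fisher are reproducible and unbiased", {
  m <- toy_model(n = 50, K = 1, m_per = 60, seed = 23)
  vc <- c(1.1, 0.9)
  pr <- probe_set(50, seed = 99)
  s1 <- stochastic_gradient_fisher(m, vc, pr)
  s2 <- stochastic_gradient_fisher(m, vc, pr)
  expect_identical(s1, s2)
  ## Gram-form Fisher estimate is symmetric PSD
  expect_equal(s1$fisher, t(s1$fisher), tolerance = 1e-10)
  expect_gt(min(eigen(s1$fisher, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)

  ## mean over independent probe sets within 3 empirical SEs of exact values
  g_exact <- gradient_exact(m, vc)
  F_exact <- fisher_info_exact(m, vc)
  reps <- lapply(1:60, function(s)
    stochastic_gradient_fisher(m, vc, probe_set(50, seed = 1000 + s)))
  G <- do.call(rbind, lapply(reps, `[[`, "gradient"))
  for (k in 1:2) {
    se <- stats::sd(G[, k]) / sqrt(nrow(G))
    expect_lt(abs(mean(G[, k]) - g_exact[k]), 3 * se)
  }
  F11 <- vapply(reps, function(r) r$fisher[1, 1], numeric(1))
  expect_lt(abs(mean(F11) - F_exact[1, 1]),
            3 * stats::sd(F11) / sqrt(length(F11)))
})

test_that("Rademacher probes give exact traces on diagonal matrices", {
  A <- diag(c(3, -1, 4, 1, 5, -9, 2, 6))
  for (s in 1:5)
    expect_equal(stochastic_trace(A, probe_set(1, seed = s, kind = "rademacher")),
                 sum(diag(A)), tolerance = 1e-12)
  ## and remain unbiased (not exact) on a non-diagonal matrix
  set.seed(24)
  M <- crossprod(matrix(stats::rnorm(64), 8, 8))
  est <- vapply(1:200, function(s)
    stochastic_trace(M, probe_set(20, seed = s, kind = "rademacher")),
    numeric(1))
  expect_lt(abs(mean(est) - sum(diag(M))),
            3 * stats::sd(est) / sqrt(length(est)))
})
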