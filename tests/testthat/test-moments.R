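test_that("HE regression solves the hand-built bordered normal equations", {
  d <- toy_dataset(n = 30, K = 1, m_per = 40, seed = 32)
  m <- mixed_model(d$y, d$grms)
  est <- he_reg(m)

  ## oracle: explicit centering projection M, system on tr terms
  n <- 30
  M <- diag(n) - matrix(1 / n, n, n)
  G <- matrix(m$Gstack[, 1], n, n)
  A1 <- M %*% G; A2 <- M
  lhs <- matrix(c(sum(diag(A1 %*% A1)), sum(diag(A1 %*% A2)),
                  sum(diag(A2 %*% A1)), sum(diag(A2 %*% A2))), 2, 2)
  yc <- drop(M %*% m$y)
  rhs <- c(drop(t(yc) %*% G %*% yc), sum(yc^2))
  expect_equal(as.numeric(est$vc_hat), solve(lhs, rhs), tolerance = 1e-8)

  ## zero phenotype: all estimates zero
  m0 <- mixed_model(stats::setNames(rep(0, n), m$ids), d$grms)
  expect_equal(as.numeric(he_reg(m0)$vc_hat), c(0, 0), tolerance = 1e-12)
})

test_that("MINQUE with an identity-proportional prior reduces to HE regression", {
  d <- toy_dataset(n = 50, K = 2, m_per = 30, seed = 33)
  m <- mixed_model(d$y, d$grms)
  he <- he_reg(m)
  for (c_scale in c(1, 3.7)) {
    mq <- minque(m, c(0, 0, c_scale))
    expect_equal(as.numeric(mq$vc_hat), as.numeric(he$vc_hat),
                 tolerance = 1e-12)
  }
})

test_that("MINQUE is stationary at the REML estimates", {
  m <- toy_model(n = 100, K = 1, m_per = 120, seed = 34)
  res <- run_reml(m, solver_options(trace_mode = "exact", tol_loglik = 1e-10,
                                    tol_grad = 1e-8, max_iter = 200))
  expect_true(res$converged)
  mq <- minque(m, as.numeric(res$vc_hat))
  expect_equal(as.numeric(mq$vc_hat), as.numeric(res$vc_hat),
               tolerance = 1e-4)
})

test_that("a component proportional to the residual structure is a collinearity error", {
  n <- 25; ids <- sprintf("i%d", seq_len(n))
  m <- mixed_model(stats::setNames(stats::rnorm(n), ids),
                   list(grmatrix(diag(n), ids, 1, "gI")))
  expect_error(he_reg(m), class = "vcpart_collinearity_error")
})

test_that("HE regression is unbiased even where it is noisy", {
  d <- toy_dataset(n = 200, K = 1, m_per = 150, seed = 35, ld_rho = 0.3)
  sc <- sim_scenario(c(chr1 = 1), h2_target = 0.5, n_traits = 300, seed = 36)
  ph <- simulate_phenotypes(d$Z, d$gm, sc)
  est <- vapply(seq_len(300), function(t) {
    m <- mixed_model(stats::setNames(ph[[t + 1]], ph$id), d$grms)
    as.numeric(he_reg(m)$vc_hat[1])
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1), 3 * se)
})

test_that("matched MINQUE priors beat identity priors under relatedness", {
  d <- toy_dataset(n = 240, K = 2, m_per = 120, seed = 37, ld_rho = 0.8,
                   family_size = 4, vc = c(chr1 = 3, chr2 = 1), h2 = 0.6)
  sc <- sim_scenario(c(chr1 = 3, chr2 = 1), h2_target = 0.6,
                     n_traits = 200, seed = 38)
  ph <- simulate_phenotypes(d$Z, d$gm, sc)
  sigma_e2 <- attr(ph, "sigma_e2")
  est <- vapply(seq_len(200), function(t) {
    m <- mixed_model(stats::setNames(ph[[t + 1]], ph$id), d$grms)
    c(as.numeric(minque(m, c(3, 1, sigma_e2))$vc_hat[1:2]),
      as.numeric(he_reg(m)$vc_hat[1:2]))
  }, numeric(4))
  sd_matched <- apply(est[1:2, ], 1, stats::sd)
  sd_identity <- apply(est[3:4, ], 1, stats::sd)
  expect_true(all(sd_matched < sd_identity))
})

test_that("LD scores match their analytic values on constructed inputs", {
  ## independent SNPs: observed ~ 1 + (m-1)/n, adjusted ~ 1
  g <- simulate_genotypes(1000, 200, n_chrom = 4, ld_rho = 0, seed = 39,
                          maf_range = c(0.1, 0.5))
  obs <- ld_scores(g$counts)
  adj <- ld_scores(g$counts, mode = "expected_adjusted")
  expect_lt(abs(mean(obs$ld_score) - (1 + 199 / 1000)), 0.03)
  expect_lt(abs(mean(adj$ld_score) - 1), 0.03)

  ## exact pairwise correlation 0.6 by construction
  set.seed(40)
  z1 <- stats::rnorm(500)
  e <- stats::residuals(stats::lm(stats::rnorm(500) ~ z1))
  z1s <- scale(z1)[, 1]; es <- scale(e)[, 1]
  pair <- cbind(a = z1s, b = 0.6 * z1s + sqrt(1 - 0.36) * es)
  lp <- ld_scores(pair)
  expect_equal(lp$ld_score, c(1.36, 1.36), tolerance = 1e-10)

  ## duplicated SNP: perfect LD pushes the score to 2 or more
  dup <- cbind(g$counts[, 1], g$counts[, 1], g$counts[, 2])
  expect_gte(ld_scores(dup)$ld_score[1], 2)

  expect_error(ld_scores(cbind(g$counts[, 1], rep(1, 1000))),
               class = "vcpart_monomorphic_error")
})

test_that("association z-scores have the stated closed forms and null calibration", {
  set.seed(41)
  n <- 400
  Zm <- scale(matrix(stats::rnorm(n * 500), n, 500))
  colnames(Zm) <- sprintf("s%d", 1:500)

  ## y equal to one unit-SD column: its z-score is sqrt(N (1 - 1/N))
  y <- Zm[, 7]
  zt <- gwas_z(Zm, y)
  expect_equal(zt$z[7], sqrt(n * (1 - 1 / n)), tolerance = 1e-10)

  ## y orthogonal to a column scores exactly zero there
  y2 <- stats::residuals(stats::lm(stats::rnorm(n) ~ Zm[, 3]))
  expect_lt(abs(gwas_z(Zm, y2)$z[3]), 1e-10)

  ## pure-noise trait: mean squared z-score near 1
  y3 <- stats::rnorm(n)
  expect_lt(abs(mean(gwas_z(Zm, y3)$z^2) - 1), 0.15)
})

test_that("the LD-score regression fit recovers h2 from its own model", {
  ld <- data.frame(snp_id = sprintf("s%d", 1:2000),
                   ld_score = 1 + stats::rexp(2000, 1 / 20))
  z0 <- data.frame(snp_id = ld$snp_id, z = rep(1, 2000))
  attr(z0, "n_gwas") <- 5000
  expect_equal(ldsc_fit(z0, ld)$h2, 0, tolerance = 1e-10)

  ## self-consistency: s_j drawn from the diagonal model with h2 = 0.5
  h2 <- 0.5; N <- 5000; M <- 2000
  set.seed(42)
  fits <- vapply(1:100, function(r) {
    v <- N * ld$ld_score * h2 / M + (1 - h2)
    z <- data.frame(snp_id = ld$snp_id, z = stats::rnorm(M, 0, sqrt(v)))
    attr(z, "n_gwas") <- N
    ldsc_fit(z, ld)$h2
  }, numeric(1))
  se <- stats::sd(fits) / sqrt(length(fits))
  expect_lt(abs(mean(fits) - h2), 3 * se)
})
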