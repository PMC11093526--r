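test_that("dogleg steps satisfy the closed-form cases", {
  ## Newton point inside the region is returned exactly
  Fm <- diag(c(2, 4)); g <- c(1, 2)
  p <- dogleg_step(g, Fm, radius = 10)
  expect_equal(as.numeric(p), solve(Fm, g), tolerance = 1e-12)
  expect_equal(attr(p, "type"), "newton")

  ## identity curvature, clipped at the boundary along the gradient
  p2 <- dogleg_step(c(3, 4), diag(2), radius = 2.5)
  expect_equal(as.numeric(p2), c(1.5, 2.0), tolerance = 1e-12)
  expect_equal(attr(p2, "type"), "cauchy")

  ## radius -> 0: direction tends to the scaled steepest ascent g/||g||
  g3 <- c(1, -2, 0.5)
  Fm3 <- crossprod(matrix(stats::rnorm(9), 3, 3)) + diag(3)
  p3 <- dogleg_step(g3, Fm3, radius = 1e-6)
  expect_equal(as.numeric(p3) / sqrt(sum(p3^2)), g3 / sqrt(sum(g3^2)),
               tolerance = 1e-6)
  expect_equal(sqrt(sum(p3^2)), 1e-6, tolerance = 1e-12)

  ## genuine dogleg interpolation has length exactly radius
  g4 <- c(4, 0); F4 <- diag(c(1, 10))
  pN <- solve(F4, g4); pC <- (sum(g4^2) / sum(g4 * (F4 %*% g4))) * g4
  r <- (sqrt(sum(pC^2)) + sqrt(sum(pN^2))) / 2
  p4 <- dogleg_step(g4, F4, radius = r)
  expect_equal(sqrt(sum(p4^2)), r, tolerance = 1e-10)

  ## singular curvature falls back to the Cauchy segment
  p5 <- dogleg_step(c(1, 1), matrix(0, 2, 2), radius = 0.3)
  expect_equal(attr(p5, "type"), "cauchy")
  expect_error(dogleg_step(c(NA, 1), diag(2), 1), class = "vcpart_numeric_error")
})

test_that("exact-trace REML matches a grid + golden-section likelihood search", {
  m <- toy_model(n = 60, K = 1, m_per = 80, seed = 25)
  res <- run_reml(m, solver_options(trace_mode = "exact", tol_loglik = 1e-8,
                                    tol_grad = 1e-6, max_iter = 100))
  expect_true(res$converged)

  ## independent oracle: coarse 2-D grid then alternating golden-section
  vy <- stats::var(m$y)
  grid <- expand.grid(eta = seq(0.05, 2.5, length.out = 40) * vy,
                      s2 = seq(0.05, 2.5, length.out = 40) * vy)
  ll <- mapply(function(a, b) tryCatch(reml_loglik(m, c(a, b)),
                                       error = function(e) -Inf),
               grid$eta, grid$s2)
  best <- grid[which.max(ll), ]
  eta <- best$eta; s2 <- best$s2
  for (sweep in 1:6) {
    eta <- stats::optimize(function(a) reml_loglik(m, c(a, s2)),
                           c(max(1e-6, eta - vy), eta + vy),
                           maximum = TRUE, tol = 1e-10)$maximum
    s2 <- stats::optimize(function(b) reml_loglik(m, c(eta, b)),
                          c(max(1e-6, s2 - vy), s2 + vy),
                          maximum = TRUE, tol = 1e-10)$maximum
  }
  expect_equal(unname(res$vc_hat[1]), eta, tolerance = 2e-3)
  expect_equal(unname(res$vc_hat[2]), s2, tolerance = 2e-3)
})

test_that("estimates are invariant to component order and equivariant in scale", {
  d <- toy_dataset(n = 80, K = 3, m_per = 40, seed = 26)
  m1 <- mixed_model(d$y, d$grms)
  r1 <- run_reml(m1, solver_options(trace_mode = "exact", tol_loglik = 1e-8))
  m2 <- mixed_model(d$y, d$grms[c(3, 1, 2)])
  r2 <- run_reml(m2, solver_options(trace_mode = "exact", tol_loglik = 1e-8))
  for (lab in c("chr1", "chr2", "chr3"))
    expect_equal(r1$vc_hat[[lab]], r2$vc_hat[[lab]], tolerance = 1e-5)

  ## y -> 3y multiplies VCs by 9, leaves heritability shares unchanged
  m3 <- mixed_model(3 * d$y, d$grms)
  r3 <- run_reml(m3, solver_options(trace_mode = "exact", tol_loglik = 1e-8))
  expect_equal(as.numeric(r3$vc_hat), 9 * as.numeric(r1$vc_hat),
               tolerance = 1e-3)
  expect_equal(r3$h2_by_component, r1$h2_by_component, tolerance = 1e-3)
})

test_that("analytical SEs come from the inverse Fisher information", {
  m <- toy_model(n = 50, K = 1, m_per = 60, seed = 27)
  res <- run_reml(m, solver_options(trace_mode = "exact"))
  expect_true(res$converged)
  Finv <- solve(res$fisher)
  expect_equal(as.numeric(res$se), sqrt(diag(Finv)), tolerance = 1e-10)
})

test_that("collinear components are flagged as a degenerate model with names", {
  d <- toy_dataset(n = 30, K = 1, m_per = 30, seed = 28)
  m <- mixed_model(d$y, list(d$grms[[1]], d$grms[[1]]))
  expect_warning(res <- run_reml(m), "collinear")
  expect_false(res$converged)
  expect_equal(res$failure_reason, "degenerate_model")
  expect_match(res$failure_detail, "chr1")

  ## identity component vs residual structure: non-identifiable
  n <- 20; ids <- sprintf("i%d", seq_len(n))
  mi <- mixed_model(stats::setNames(stats::rnorm(n), ids),
                    list(grmatrix(diag(n), ids, 1, "gI")))
  expect_warning(ri <- run_reml(mi), "collinear")
  expect_equal(ri$failure_reason, "degenerate_model")
  expect_match(ri$failure_detail, "residual")
})

test_that("the trust region rescues steps that leave the parameter space", {
  ## a truly null component drives raw Fisher steps toward non-PD territory
  d <- toy_dataset(n = 120, K = 2, m_per = 60, seed = 29,
                   vc = c(chr1 = 1, chr2 = 0))
  m <- mixed_model(d$y, d$grms)
  res <- run_reml(m, solver_options(trace_mode = "exact"))
  expect_true(res$converged || res$failure_reason == "exploding_gradient")
  if (res$converged) {
    ## safeguarding had to activate at least once
    expect_true(any(res$iter_log$step_type %in% c("cauchy", "dogleg")) ||
                all(res$iter_log$step_type == "newton"))
    expect_lt(abs(res$vc_hat[["chr2"]]), 3 * res$se[["chr2"]] + 0.5)
  }
})

test_that("results tables and run logs are written in the documented schema", {
  m <- toy_model(n = 40, K = 1, m_per = 40, seed = 30)
  res <- run_reml(m, solver_options(trace_mode = "exact"))
  prefix <- tempfile("res")
  withr::defer(unlink(paste0(prefix, c(".csv", ".log.csv"))))
  write_results(res, prefix)
  tab <- utils::read.csv(paste0(prefix, ".csv"))
  expect_named(tab, c("component", "vc_hat", "se", "h2", "h2_se"))
  expect_equal(tab$component, c("chr1", "residual"))
  log <- utils::read.csv(paste0(prefix, ".log.csv"))
  expect_true(all(c("iteration", "loglik", "grad_norm", "radius",
                    "step_type") %in% names(log)))
  expect_true(all(diff(log$loglik) > -1e-8))   # monotone accepted path
})

test_that("trace-mode comparison reports differences and noise flags", {
  m <- toy_model(n = 60, K = 1, m_per = 60, seed = 31)
  opts <- solver_options(probes = probe_set(200, seed = 5))
  cmp <- compare_trace_modes(m, opts)
  expect_true(cmp$exact_converged && cmp$stochastic_converged)
  expect_named(cmp$table, c("component", "exact", "stochastic", "diff",
                            "abs_diff_over_se"))

  ## identical probe seeds: stochastic mode is exactly reproducible
  opt_s <- solver_options(trace_mode = "stochastic",
                          probes = probe_set(40, seed = 11))
  r1 <- run_reml(m, opt_s); r2 <- run_reml(m, opt_s)
  expect_identical(r1$vc_hat, r2$vc_hat)

  ## B = 1 is flagged as high Monte-Carlo noise
  cmp1 <- compare_trace_modes(m, solver_options(probes = probe_set(1, seed = 2)))
  expect_true(cmp1$high_noise)
})
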