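#' Solver options for Fisher-scoring REML
#'
#' @param max_iter maximum Fisher-scoring iterations.
#' @param tol_loglik absolute restricted-log-likelihood change declaring
#'   convergence (on an accepted step).
#' @param tol_grad tolerance on the scaled Newton step ||F^{-1} grad||_inf
#'   relative to the parameter scale.
#' @param initial_radius initial trust-region radius; default
#'   ||starting vc|| / 10.
#' @param trace_mode `"exact"` or `"stochastic"` trace evaluation.
#' @param probes a [probe_set()] for stochastic mode; fresh probes are drawn
#'   each iteration from a seed sequence derived from `probes$seed`.
#' @param starts `"naive"` (equal eta_k summing to 0.5 Var(y), residual
#'   0.5 Var(y)) or a numeric vector of length K+1.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(max_iter = 50L, tol_loglik = 1e-4, tol_grad = 1e-3,
                           initial_radius = NULL,
                           trace_mode = c("exact", "stochastic"),
                           probes = probe_set(100L, seed = 1L),
                           starts = "naive") {
  if (max_iter < 1 || tol_loglik <= 0 || tol_grad <= 0)
    stop_vcpart("max_iter >= 1 and positive tolerances required",
                "vcpart_parameter_error")
  structure(list(max_iter = as.integer(max_iter), tol_loglik = tol_loglik,
                 tol_grad = tol_grad, initial_radius = initial_radius,
                 trace_mode = match.arg(trace_mode), probes = probes,
                 starts = starts),
            class = "solver_options")
}

#' Trust-region dogleg step
#'
#' Minimizes the local quadratic model m(p) = -g'p + 1/2 p'Fp (i.e. maximizes
#' the predicted log-likelihood gain) over the dogleg path within
#' ||p|| <= radius. Returns the Newton point F^{-1}g when it lies inside the
#' region; otherwise the dogleg interpolation between the Cauchy point and
#' the Newton point at ||p|| = radius. Falls back to the Cauchy segment when
#' F is singular or the Newton step is not an ascent direction.
#'
#' @param grad gradient g (ascent direction of the likelihood).
#' @param fisher symmetric curvature matrix F.
#' @param radius trust-region radius (> 0).
#' @return Step vector with attribute `"type"` in
#'   `c("newton", "dogleg", "cauchy")`.
#' @export
dogleg_step <- function(grad, fisher, radius) {
  if (!all(is.finite(grad)) || !all(is.finite(fisher)) || !is.finite(radius) ||
      radius <= 0)
    stop_vcpart("non-finite inputs to dogleg_step", "vcpart_numeric_error")
  g <- as.numeric(grad)
  gnorm <- sqrt(sum(g^2))
  cauchy_clip <- function() {
    structure(radius * g / gnorm, type = "cauchy")
  }
  if (gnorm == 0) return(structure(numeric(length(g)), type = "newton"))
  p_N <- tryCatch(solve(fisher, g), error = function(e) NULL)
  gFg <- sum(g * (fisher %*% g))
  newton_ok <- !is.null(p_N) && all(is.finite(p_N)) && sum(g * p_N) > 0
  if (newton_ok && sqrt(sum(p_N^2)) <= radius)
    return(structure(p_N, type = "newton"))
  if (gFg <= 0) return(cauchy_clip())
  p_C <- (gnorm^2 / gFg) * g
  pCn <- sqrt(sum(p_C^2))
  if (!newton_ok || pCn >= radius) {
    step <- if (pCn >= radius) cauchy_clip() else structure(p_C, type = "cauchy")
    return(step)
  }
  ## dogleg: p_C + t (p_N - p_C) with ||p|| = radius, t in (0, 1)
  d <- p_N - p_C
  a <- sum(d^2); b <- 2 * sum(p_C * d); cc <- pCn^2 - radius^2
  t_sol <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  structure(p_C + t_sol * d, type = "dogleg")
}

## pairwise cosine similarity of components (incl. residual structure);
## near-1 cosines mean a non-identifiable model.
find_collinear_components <- function(model, tol = 1e-8) {
  n <- model$n
  labs <- c(model$labels, "residual")
  if (all(vapply(model$G, identical, logical(1), "stacked"))) {
    Rvec <- numeric(n * n)
    Rvec[seq(1, n * n, by = n + 1)] <- model$R_diag
    M <- cbind(model$Gstack, Rvec)
    gram <- crossprod(M)
  } else {
    mats <- lapply(seq_len(model$K), function(k)
      as.numeric(dense_component(model, k)))
    mats[[model$K + 1]] <- as.numeric(diag(model$R_diag, n))
    gram <- crossprod(do.call(cbind, mats))
  }
  nrm <- sqrt(diag(gram))
  cs <- gram / tcrossprod(nrm)
  cs[lower.tri(cs, diag = TRUE)] <- 0
  bad <- which(cs > 1 - tol, arr.ind = TRUE)
  if (nrow(bad) == 0) return(NULL)
  c(labs[bad[1, 1]], labs[bad[1, 2]])
}

#' Fisher-scoring REML with trust-region dogleg safeguarding
#'
#' Iterates Fisher scoring on the variance components of a [mixed_model()].
#' Each iteration evaluates the restricted log-likelihood, gradient and
#' Fisher information (exactly, or with stochastic trace estimates), proposes
#' a dogleg step, and retries with a shrunken trust radius whenever the
#' proposal leaves the positive-definite parameter space or decreases the
#' (always exactly evaluated) restricted log-likelihood. The radius expands
#' (x2) after a boundary step with actual/predicted improvement > 0.75 and
#' shrinks (x0.25) below 0.25. Negative variance components are allowed as
#' long as V stays positive definite; no boxing at zero.
#'
#' Failure modes are reported, never silently returned: `max_iter`,
#' `exploding_gradient` (gradient norm growing more than tenfold across
#' three consecutive iterations, the symptom of a true boundary VC of 0),
#' and `degenerate_model` (duplicated/collinear components, detected up
#' front and named).
#'
#' @param model a `mixed_model`.
#' @param options a [solver_options()].
#' @return A `reml_result`: list with `vc_hat` (named, residual last), `se`,
#'   `fisher`, `loglik_path`, `converged`, `n_iter`, `failure_reason`,
#'   `h2_by_component` (with `h2_se`), `h2_total` (+ SE), `beta_hat`, and
#'   `iter_log` (iteration, loglik, grad_norm, radius, step_type).
#' @export
run_reml <- function(model, options = solver_options()) {
  stopifnot(inherits(model, "mixed_model"), inherits(options, "solver_options"))
  K <- model$K
  comp_names <- c(model$labels, "residual")

  coll <- if (isTRUE(model$collinear_checked)) model$collinear_pair
          else find_collinear_components(model)
  if (!is.null(coll))
    return(reml_failure(model, "degenerate_model",
                        sprintf("components '%s' and '%s' are collinear",
                                coll[1], coll[2])))

  vary <- stats::var(model$y)
  vc <- if (identical(options$starts, "naive"))
    c(rep(0.5 * vary / K, K), 0.5 * vary)
  else {
    stopifnot(is.numeric(options$starts), length(options$starts) == K + 1)
    as.numeric(options$starts)
  }
  radius <- options$initial_radius %||% (sqrt(sum(vc^2)) / 10)
  stochastic <- options$trace_mode == "stochastic"

  h <- tryCatch(assemble_V(model, vc), vcpart_not_pd = function(e) NULL)
  if (is.null(h))
    return(reml_failure(model, "degenerate_model",
                        "starting values outside the parameter space"))

  loglik_path <- h$loglik
  grad_norms <- numeric(0)
  iter_log <- list()
  converged <- FALSE
  failure <- "none"
  gF <- NULL
  iter <- 0L
  small_gain_streak <- 0L   # consecutive below-tolerance gains (stochastic)

  for (iter in seq_len(options$max_iter)) {
    gF <- eval_grad_fisher(model, vc, h, options, iter)
    g <- gF$gradient
    gnorm <- sqrt(sum(g^2))
    grad_norms <- c(grad_norms, gnorm)

    ## exploding gradient: >10x growth across 3 consecutive iterations
    ni <- length(grad_norms)
    if (ni >= 4 && grad_norms[ni] > 10 * grad_norms[ni - 3] &&
        all(diff(grad_norms[(ni - 3):ni]) > 0)) {
      failure <- "exploding_gradient"
      break
    }

    ## gradient-based convergence: scaled Newton step small
    delta <- tryCatch(solve(gF$fisher, g), error = function(e) NULL)
    scale_ref <- pmax(abs(vc), 1e-3 * vary)
    if (!is.null(delta) && max(abs(delta) / scale_ref) < options$tol_grad) {
      converged <- TRUE
      iter_log[[iter]] <- data.frame(iteration = iter, loglik = h$loglik,
                                     grad_norm = gnorm, radius = radius,
                                     step_type = "none")
      break
    }

    accepted <- FALSE
    step_type <- "none"
    for (attempt in seq_len(40L)) {
      p <- dogleg_step(g, gF$fisher, radius)
      step_type <- attr(p, "type")
      vc_new <- vc + as.numeric(p)
      h_new <- tryCatch(assemble_V(model, vc_new),
                        vcpart_not_pd = function(e) NULL)
      if (is.null(h_new)) { radius <- radius * 0.25; next }
      pred <- sum(g * p) - 0.5 * sum(p * (gF$fisher %*% p))
      act <- h_new$loglik - h$loglik
      if (act < -1e-10) { radius <- radius * 0.25; next }
      hit_boundary <- sqrt(sum(p^2)) >= 0.99 * radius
      if (!stochastic) {
        ## classical ratio-based radius update
        ratio <- if (pred > 0) act / pred else 1
        if (ratio > 0.75 && hit_boundary) radius <- radius * 2
        else if (ratio < 0.25) radius <- radius * 0.25
      } else if (attempt == 1L && hit_boundary) {
        ## noisy predicted gains bias the classical ratio low; expand on a
        ## clean boundary acceptance instead (shrinks happen on rejection)
        radius <- radius * 2
      }
      vc <- vc_new
      h <- h_new
      accepted <- TRUE
      break
    }
    iter_log[[iter]] <- data.frame(iteration = iter, loglik = h$loglik,
                                   grad_norm = gnorm, radius = radius,
                                   step_type = step_type)
    if (!accepted) { failure <- "max_iter"; break }
    loglik_path <- c(loglik_path, h$loglik)
    gain <- utils::tail(diff(loglik_path), 1)
    if (abs(gain) < options$tol_loglik) {
      small_gain_streak <- small_gain_streak + 1L
      ## a sub-tolerance gain after rejections can be a shrink-phase
      ## artefact under noisy gradients; then require two in a row
      if (!stochastic || attempt == 1L || small_gain_streak >= 2L) {
        converged <- TRUE
        break
      }
    } else small_gain_streak <- 0L
    if (radius < 1e-5 * max(sqrt(sum(vc^2)), 1e-12)) {
      converged <- TRUE    # progress below the Monte-Carlo noise floor
      break
    }
  }
  if (!converged && failure == "none") failure <- "max_iter"

  ## SEs and heritability shares from the Fisher information at vc_hat
  F_final <- eval_grad_fisher(model, vc, h, options, iter + 1L)$fisher
  Finv <- tryCatch(solve(F_final), error = function(e)
    matrix(NA_real_, K + 1, K + 1))
  se <- sqrt(pmax(diag(Finv), 0))
  d <- model_mean_diags(model)
  h2 <- heritability_shares(vc, d, Finv)

  beta_hat <- drop(backsolve(h$cX, backsolve(h$cX, crossprod(model$X,
    backsolve(h$U, backsolve(h$U, model$y, transpose = TRUE))),
    transpose = TRUE)))

  structure(list(
    vc_hat = stats::setNames(vc, comp_names),
    se = stats::setNames(se, comp_names),
    fisher = F_final,
    loglik_path = loglik_path,
    converged = converged,
    n_iter = iter,
    failure_reason = failure,
    failure_detail = NULL,
    h2_by_component = h2$by_component,
    h2_se = h2$by_component_se,
    h2_total = h2$total,
    h2_total_se = h2$total_se,
    beta_hat = beta_hat,
    iter_log = do.call(rbind, iter_log),
    labels = comp_names,
    options = options
  ), class = "reml_result")
}

eval_grad_fisher <- function(model, vc, handle, options, iter) {
  if (options$trace_mode == "exact") {
    P <- projection_dense(model, handle)
    K <- model$K
    A <- vector("list", K + 1)
    for (k in seq_len(K)) A[[k]] <- P %*% dense_component(model, k)
    A[[K + 1]] <- P * rep(model$R_diag, each = model$n)
    g <- numeric(K + 1)
    for (k in seq_len(K + 1))
      g[k] <- -0.5 * (sum(diag(A[[k]])) - comp_quad(model, k, handle$Py))
    F_mat <- matrix(0, K + 1, K + 1)
    for (k in seq_len(K + 1))
      for (l in k:(K + 1)) {
        F_mat[k, l] <- 0.5 * sum(A[[k]] * t(A[[l]]))
        F_mat[l, k] <- F_mat[k, l]
      }
    list(gradient = g, fisher = F_mat)
  } else {
    pr <- options$probes
    pr_i <- probe_set(pr$count, seed = derive_seed(pr$seed, iter), kind = pr$kind)
    stochastic_gradient_fisher(model, vc, pr_i, handle = handle)
  }
}

heritability_shares <- function(vc, mean_diags, Finv) {
  K <- length(vc) - 1
  contrib <- vc * mean_diags                 # per-component variance on y scale
  S <- sum(contrib)
  h2 <- contrib[seq_len(K)] / S
  grad_list <- lapply(seq_len(K), function(k) {
    gk <- -contrib[k] * mean_diags / S^2
    gk[k] <- gk[k] + mean_diags[k] / S
    gk
  })
  h2_se <- vapply(grad_list, function(gk)
    sqrt(max(0, sum(gk * (Finv %*% gk)))), numeric(1))
  gt <- Reduce(`+`, grad_list)
  list(by_component = h2, by_component_se = h2_se,
       total = sum(h2),
       total_se = sqrt(max(0, sum(gt * (Finv %*% gt)))))
}

reml_failure <- function(model, reason, detail) {
  K <- model$K
  comp_names <- c(model$labels, "residual")
  warning(sprintf("REML failed (%s): %s", reason, detail), call. = FALSE)
  structure(list(
    vc_hat = stats::setNames(rep(NA_real_, K + 1), comp_names),
    se = stats::setNames(rep(NA_real_, K + 1), comp_names),
    fisher = NULL, loglik_path = numeric(0), converged = FALSE,
    n_iter = 0L, failure_reason = reason, failure_detail = detail,
    h2_by_component = rep(NA_real_, K), h2_se = rep(NA_real_, K),
    h2_total = NA_real_, h2_total_se = NA_real_, beta_hat = NULL,
    iter_log = NULL, labels = comp_names, options = NULL
  ), class = "reml_result")
}

#' @export
print.reml_result <- function(x, ...) {
  cat(sprintf("reml_result: %s after %d iteration(s)%s\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              if (x$failure_reason != "none")
                sprintf(" [%s]", x$failure_reason) else ""))
  if (all(is.finite(x$vc_hat))) {
    df <- data.frame(component = x$labels, vc = x$vc_hat, se = x$se,
                     row.names = NULL)
    K <- length(x$vc_hat) - 1
    df$h2 <- c(x$h2_by_component, NA)
    df$h2_se <- c(x$h2_se, NA)
    print(df, digits = 4)
    cat(sprintf("total h2 = %.4f (SE %.4f)\n", x$h2_total, x$h2_total_se))
  }
  invisible(x)
}

#' Write REML (or moment-estimator) results and run log to disk
#'
#' `<prefix>.csv` holds the per-component table (component, vc_hat, se, h2,
#' h2_se); `<prefix>.log.csv` holds the iteration trace for REML results.
#'
#' @param result a `reml_result` or `moment_estimate`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_results <- function(result, prefix) {
  if (inherits(result, "reml_result")) {
    K <- length(result$vc_hat) - 1
    df <- data.frame(component = result$labels, vc_hat = result$vc_hat,
                     se = result$se,
                     h2 = c(result$h2_by_component, NA),
                     h2_se = c(result$h2_se, NA), row.names = NULL)
    utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
    if (!is.null(result$iter_log))
      utils::write.csv(result$iter_log, paste0(prefix, ".log.csv"),
                       row.names = FALSE)
  } else {
    df <- data.frame(component = names(result$vc_hat),
                     vc_hat = as.numeric(result$vc_hat),
                     se = NA_real_, h2 = NA_real_, h2_se = NA_real_,
                     row.names = NULL)
    utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  }
  invisible(prefix)
}

#' Compare exact- and stochastic-trace REML on the same model
#'
#' Runs both modes and reports componentwise differences of the estimates and
#' their ratio to the exact-mode analytical SEs. A `high_noise` flag is set
#' when the probe count is small (< 10) or any difference exceeds one SE.
#'
#' @param model a `mixed_model`.
#' @param options a [solver_options()]; its `probes` are used for the
#'   stochastic run.
#' @return List with `table` (component, exact, stochastic, diff,
#'   abs_diff_over_se), `exact`, `stochastic` (the two `reml_result`s), and
#'   flags `exact_converged`, `stochastic_converged`, `high_noise`.
#' @export
compare_trace_modes <- function(model, options = solver_options()) {
  opt_e <- options; opt_e$trace_mode <- "exact"
  opt_s <- options; opt_s$trace_mode <- "stochastic"
  res_e <- run_reml(model, opt_e)
  res_s <- run_reml(model, opt_s)
  tab <- data.frame(
    component = res_e$labels,
    exact = as.numeric(res_e$vc_hat),
    stochastic = as.numeric(res_s$vc_hat),
    diff = as.numeric(res_s$vc_hat - res_e$vc_hat),
    abs_diff_over_se = abs(as.numeric(res_s$vc_hat - res_e$vc_hat)) /
      as.numeric(res_e$se),
    row.names = NULL)
  list(table = tab, exact = res_e, stochastic = res_s,
       exact_converged = res_e$converged,
       stochastic_converged = res_s$converged,
       high_noise = options$probes$count < 10 ||
         any(is.finite(tab$abs_diff_over_se) & tab$abs_diff_over_se > 1))
}
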