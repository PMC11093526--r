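#' Assemble a multi-component linear mixed model
#'
#' The model is y = X beta + g + e with g ~ N(0, sum_k G_k eta_k) and
#' e ~ N(0, R sigma_e^2), R diagonal. Each G_k is a precomputed covariance
#' structure matrix, typically a genomic relationship matrix for one SNP
#' category. The variance-component parameter space is every (eta, sigma_e^2)
#' for which V = sum_k G_k eta_k + R sigma_e^2 is positive definite;
#' individual components may be negative.
#'
#' Components are aligned to `ids` by individual identifier, never by
#' position. Streamed GRMs (`grm_stream`) are accepted for the memory-saving
#' path but must already be stored in the requested id order.
#'
#' @param y numeric phenotype vector; names used as ids when `ids` is NULL.
#' @param grms list of `grmatrix` / `grm_stream` components (K >= 1).
#' @param X optional covariate matrix (an intercept column is always added).
#' @param R_diag positive residual weights (default all 1).
#' @param ids individual identifiers ordering y/X rows.
#' @return An object of class `mixed_model`.
#' @export
mixed_model <- function(y, grms, X = NULL, R_diag = NULL, ids = NULL) {
  if (inherits(grms, "grmatrix") || inherits(grms, "grm_stream"))
    grms <- list(grms)
  stopifnot(length(grms) >= 1)
  n <- length(y)
  ids <- as.character(ids %||% names(y) %||% grm_ids(grms[[1]]))
  if (length(ids) != n)
    stop_vcpart("ids length must match y", "vcpart_parameter_error")

  ## dense components live as columns of one n^2 x K stack (single-copy
  ## storage, lets V assembly be one matrix-vector product); streamed
  ## components stay as on-disk handles
  G <- vector("list", length(grms))
  Gstack <- matrix(0, n * n, length(grms))       # vec(G_k) columns
  Gtall <- matrix(0, n * length(grms), n)        # G_k stacked row-blocks
  mean_diags <- numeric(length(grms))
  labels <- character(length(grms))
  for (k in seq_along(grms)) {
    g <- grms[[k]]
    labels[k] <- grm_label(g)
    if (!all(ids %in% grm_ids(g)))
      stop_vcpart(sprintf("component '%s' does not cover the %d phenotyped ids",
                          labels[k], n), "vcpart_parameter_error")
    if (inherits(g, "grm_stream")) {
      if (!identical(grm_ids(g), ids))
        stop_vcpart(sprintf("streamed GRM '%s' must be stored in phenotype id order",
                            labels[k]), "vcpart_parameter_error")
      G[[k]] <- g
      mean_diags[k] <- grm_mean_diag(g)
    } else {
      M <- as.matrix(g)
      perm <- match(ids, grm_ids(g))
      M <- M[perm, perm]
      Gstack[, k] <- as.numeric(M)
      Gtall[(k - 1L) * n + seq_len(n), ] <- M
      G[[k]] <- "stacked"
      mean_diags[k] <- mean(diag(M))
    }
  }
  if (anyDuplicated(labels))
    labels <- make.unique(labels)

  Xf <- cbind(intercept = rep(1, n), if (!is.null(X)) as.matrix(X))
  if (nrow(Xf) != n)
    stop_vcpart("X must have one row per individual", "vcpart_parameter_error")
  if (qr(Xf)$rank < ncol(Xf))
    stop_vcpart("fixed-effect design X is rank deficient", "vcpart_rank_error")
  R_diag <- R_diag %||% rep(1, n)
  if (length(R_diag) != n || any(R_diag <= 0))
    stop_vcpart("R_diag must be positive, length n", "vcpart_parameter_error")

  model <- structure(
    list(y = as.numeric(y), X = Xf, R_diag = as.numeric(R_diag),
         G = G, Gstack = Gstack, Gtall = Gtall, mean_diags = mean_diags,
         labels = labels, ids = ids, n = n, K = length(G)),
    class = "mixed_model")
  ## identifiability scan once at construction (solvers reuse the verdict)
  model$collinear_pair <- find_collinear_components(model)
  model$collinear_checked <- TRUE
  model
}

#' Replace the phenotype of an assembled model
#'
#' Reuses the (potentially large) component stacks of an existing
#' `mixed_model` for a new trait measured on the same individuals, avoiding
#' the cost of re-assembling the GRMs. The new phenotype must cover exactly
#' the model's individuals; values are realigned by id.
#'
#' @param model a `mixed_model`.
#' @param y named numeric vector (names = individual ids).
#' @return The model with `y` replaced.
#' @export
set_phenotype <- function(model, y) {
  stopifnot(inherits(model, "mixed_model"))
  if (!is.null(names(y))) {
    idx <- match(model$ids, names(y))
    if (anyNA(idx))
      stop_vcpart("new phenotype does not cover the model's individuals",
                  "vcpart_parameter_error")
    y <- y[idx]
  } else if (length(y) != model$n)
    stop_vcpart("unnamed phenotype must have length n", "vcpart_parameter_error")
  model$y <- as.numeric(y)
  model
}

#' @export
print.mixed_model <- function(x, ...) {
  cat(sprintf("mixed_model: n = %d, K = %d component(s) [%s], p = %d fixed effect(s)\n",
              x$n, x$K, paste(x$labels, collapse = ", "), ncol(x$X)))
  invisible(x)
}

model_mean_diags <- function(model) {
  c(model$mean_diags, mean(model$R_diag))
}

## G_k %*% W for component k (k = K+1 is the residual structure R)
comp_matmul <- function(model, k, W) {
  if (k == model$K + 1) return(W * model$R_diag)
  g <- model$G[[k]]
  if (identical(g, "stacked"))
    matrix(model$Gstack[, k], model$n, model$n) %*% W
  else grm_matmul(g, W)
}

#' Assemble and factorize V for a variance-component vector
#'
#' Builds V = sum_k G_k eta_k + R sigma_e^2 and returns its Cholesky-based
#' handle supporting solves and the log-determinant, plus the cached
#' projection quantities used by the restricted likelihood. Signals a
#' `vcpart_not_pd` condition when V is not positive definite (the solver
#' treats this as "outside the parameter space", not as a fatal error).
#'
#' @param model a `mixed_model`.
#' @param vc numeric length K+1: (eta_1..eta_K, sigma_e2).
#' @return A `vc_chol` handle: list with `U` (upper Cholesky factor,
#'   V = U'U), `logdet_V`, `loglik` (restricted log-likelihood), `Py`, and
#'   internals used by [projection_apply()].
#' @export
assemble_V <- function(model, vc) {
  stopifnot(inherits(model, "mixed_model"))
  K <- model$K
  if (length(vc) != K + 1)
    stop_vcpart(sprintf("vc must have length K+1 = %d", K + 1),
                "vcpart_parameter_error")
  n <- model$n
  stacked <- vapply(model$G, identical, logical(1), "stacked")
  eta <- vc[seq_len(K)]
  V <- if (all(stacked)) matrix(model$Gstack %*% eta, n, n)
  else if (any(stacked))
    matrix(model$Gstack %*% ifelse(stacked, eta, 0), n, n)
  else matrix(0, n, n)
  for (k in which(!stacked)) V <- grm_add_into(V, model$G[[k]], vc[k])
  diag(V) <- diag(V) + vc[K + 1] * model$R_diag
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U))
    stop(structure(
      class = c("vcpart_not_pd", "vcpart_error", "error", "condition"),
      list(message = "V is not positive definite (outside parameter space)",
           call = sys.call(-1), vc = vc)))
  X <- model$X
  VinvX <- backsolve(U, backsolve(U, X, transpose = TRUE))
  XtVinvX <- crossprod(X, VinvX)
  cX <- tryCatch(chol(XtVinvX), error = function(e)
    stop_vcpart("X'V^{-1}X is singular: fixed-effect design X is rank deficient",
                "vcpart_rank_error"))
  Viy <- backsolve(U, backsolve(U, model$y, transpose = TRUE))
  XtViy <- crossprod(X, Viy)
  Py <- Viy - VinvX %*% backsolve(cX, backsolve(cX, XtViy, transpose = TRUE))
  Py <- drop(Py)
  logdet_V <- 2 * sum(log(diag(U)))
  logdet_XtVinvX <- 2 * sum(log(diag(cX)))
  ## Harville's restricted likelihood; the log|X'X| term makes it exactly
  ## invariant under X -> XA for invertible A
  logdet_XtX <- 2 * sum(log(diag(chol(crossprod(X)))))
  ll <- -0.5 * (logdet_V + logdet_XtVinvX - logdet_XtX + sum(model$y * Py))
  Q <- t(backsolve(cX, t(VinvX), transpose = TRUE))  # P = V^{-1} - QQ'
  structure(list(U = U, VinvX = VinvX, cX = cX, Q = Q, Py = Py,
                 logdet_V = logdet_V, logdet_XtVinvX = logdet_XtVinvX,
                 loglik = ll, vc = vc),
            class = "vc_chol")
}

#' @export
print.vc_chol <- function(x, ...) {
  cat(sprintf("vc_chol: n = %d, log|V| = %.4f, restricted loglik = %.4f\n",
              nrow(x$U), x$logdet_V, x$loglik))
  invisible(x)
}

#' Apply the REML projection P to a vector or matrix
#'
#' P = V^{-1} - V^{-1}X (X'V^{-1}X)^{-1} X'V^{-1} is applied through
#' factorization solves; P itself is never formed. X'Pw = 0 for every w.
#'
#' @param model a `mixed_model`.
#' @param handle a `vc_chol` from [assemble_V()].
#' @param w numeric vector or matrix with n rows.
#' @return P w, same shape as `w`.
#' @export
projection_apply <- function(model, handle, w) {
  w <- as.matrix(w)
  Viw <- backsolve(handle$U, backsolve(handle$U, w, transpose = TRUE))
  XtViw <- crossprod(model$X, Viw)
  out <- Viw - handle$VinvX %*%
    backsolve(handle$cX, backsolve(handle$cX, XtViw, transpose = TRUE))
  if (ncol(out) == 1) drop(out) else out
}

#' Restricted log-likelihood of a variance-component vector
#'
#' -1/2 (log|V| + log|X'V^{-1}X| + y'Py), constants dropped. Invariant under
#' reparameterization X -> XA for invertible A.
#'
#' @inheritParams assemble_V
#' @return Scalar log-likelihood (finite inside the parameter space).
#' @export
reml_loglik <- function(model, vc) assemble_V(model, vc)$loglik

## Dense projection matrix; used by the exact trace path (small/medium n).
projection_dense <- function(model, handle) {
  chol2inv(handle$U) - tcrossprod(handle$Q)
}

## quadratic form (Py)' G_k (Py)
comp_quad <- function(model, k, Py) {
  sum(Py * comp_matmul(model, k, Py))
}

#' Exact REML gradient
#'
#' Component k of the score is -1/2 (tr(P G_k) - y'P G_k P y); the residual
#' component uses structure matrix R. Uses a dense projection matrix, so it
#' is intended for moderate n.
#'
#' @inheritParams assemble_V
#' @return Numeric vector of length K+1.
#' @export
gradient_exact <- function(model, vc) {
  h <- assemble_V(model, vc)
  P <- projection_dense(model, h)
  K <- model$K
  g <- numeric(K + 1)
  for (k in seq_len(K)) {
    Gk <- dense_component(model, k)
    g[k] <- -0.5 * (sum(P * Gk) - comp_quad(model, k, h$Py))
  }
  g[K + 1] <- -0.5 * (sum(diag(P) * model$R_diag) - comp_quad(model, K + 1, h$Py))
  g
}

dense_component <- function(model, k) {
  if (k == model$K + 1) return(diag(model$R_diag, model$n))
  g <- model$G[[k]]
  if (identical(g, "stacked")) matrix(model$Gstack[, k], model$n, model$n)
  else as.matrix(read_grm(g$path))
}

#' Exact Fisher information of the variance components
#'
#' F_kl = 1/2 tr(P G_k P G_l), symmetric positive semidefinite. The residual
#' structure R is the (K+1)-th component.
#'
#' @inheritParams assemble_V
#' @return (K+1) x (K+1) matrix.
#' @export
fisher_info_exact <- function(model, vc) {
  h <- assemble_V(model, vc)
  P <- projection_dense(model, h)
  K <- model$K
  A <- vector("list", K + 1)
  for (k in seq_len(K)) A[[k]] <- P %*% dense_component(model, k)
  A[[K + 1]] <- P * rep(model$R_diag, each = model$n)  # P %*% diag(R)
  F_mat <- matrix(0, K + 1, K + 1)
  for (k in seq_len(K + 1))
    for (l in k:(K + 1)) {
      F_mat[k, l] <- 0.5 * sum(A[[k]] * t(A[[l]]))
      F_mat[l, k] <- F_mat[k, l]
    }
  F_mat
}

#' Define a stochastic-trace probe set
#'
#' @param count number of probes B (>= 1).
#' @param seed integer seed controlling the probe draws.
#' @param kind `"model_draws"` (y_b ~ N(0, V); Gram-form Fisher estimate,
#'   symmetric PSD by construction) or `"rademacher"` (plain Hutchinson
#'   probes; kept for unit-level checks).
#' @return An object of class `probe_set`.
#' @export
probe_set <- function(count = 100L, seed = 1L,
                      kind = c("model_draws", "rademacher")) {
  if (count < 1) stop_vcpart("probe count must be >= 1", "vcpart_parameter_error")
  structure(list(count = as.integer(count), seed = as.integer(seed),
                 kind = match.arg(kind)),
            class = "probe_set")
}

#' Stochastic (probe-based) REML gradient and Fisher information
#'
#' Trace terms are replaced by Monte-Carlo estimates. With model draws,
#' y_b = U' z_b (so Cov(y_b) = V) and, using P V P = P,
#' tr(P G_k) is estimated by mean_b y_b' P G_k P y_b and tr(P G_k P G_l) by
#' mean_b (G_k P y_b)' P (G_l P y_b); the Fisher estimate is then a Gram
#' matrix, hence symmetric PSD, and both estimators are unbiased. The
#' data-dependent quadratic forms y'P G_k P y use the actual phenotype and
#' are exact. Deterministic given the probe seed.
#'
#' @inheritParams assemble_V
#' @param probes a [probe_set()].
#' @param handle optional precomputed `vc_chol` for `vc`.
#' @return List with `gradient` (length K+1), `fisher` ((K+1) x (K+1)), and
#'   `trace_est` (the estimated tr(P G_k)).
#' @export
stochastic_gradient_fisher <- function(model, vc, probes, handle = NULL) {
  stopifnot(inherits(probes, "probe_set"))
  h <- handle %||% assemble_V(model, vc)
  n <- model$n; K <- model$K; B <- probes$count
  Zp <- with_local_seed(probes$seed, {
    if (probes$kind == "rademacher")
      matrix(sample(c(-1, 1), n * B, replace = TRUE), n, B)
    else matrix(stats::rnorm(n * B), n, B)
  })

  if (probes$kind == "model_draws") {
    Y <- crossprod(h$U, Zp)              # y_b = U' z_b ~ N(0, V)
    W <- projection_apply(model, h, Y)   # P y_b
    W <- cbind(W, h$Py)                  # last column: actual data
    tr_est <- numeric(K + 1)
    quad <- numeric(K + 1)
    ## u_kb' P u_lb = (L^{-1}u_kb)'(L^{-1}u_lb) - (Q'u_kb)'(Q'u_lb); stack
    ## the half-solved probes columnwise so one crossprod yields all pairs
    Smat <- matrix(0, n * B, K + 1)
    Cmat <- matrix(0, ncol(model$X) * B, K + 1)
    all_stacked <- all(vapply(model$G, identical, logical(1), "stacked"))
    Ustack <- if (all_stacked) model$Gtall %*% W   # all G_k W in one product
    for (k in seq_len(K + 1)) {
      Uk <- if (k == K + 1) W * model$R_diag
      else if (all_stacked) Ustack[(k - 1L) * n + seq_len(n), , drop = FALSE]
      else comp_matmul(model, k, W)
      tr_est[k] <- sum(W[, seq_len(B)] * Uk[, seq_len(B)]) / B
      quad[k] <- sum(W[, B + 1] * Uk[, B + 1])
      Ukp <- Uk[, seq_len(B), drop = FALSE]
      Smat[, k] <- backsolve(h$U, Ukp, transpose = TRUE)
      Cmat[, k] <- crossprod(h$Q, Ukp)
    }
    F_mat <- 0.5 * (crossprod(Smat) - crossprod(Cmat)) / B
  } else {
    ## Hutchinson probes against P-products: tr(PG_k) ~ mean z'(P G_k)z
    W <- projection_apply(model, h, Zp)  # P z_b
    tr_est <- numeric(K + 1)
    quad <- numeric(K + 1)
    Slist <- vector("list", K + 1)       # G_k z_b
    Mlist <- vector("list", K + 1)       # G_k P z_b
    for (k in seq_len(K + 1)) {
      Slist[[k]] <- comp_matmul(model, k, Zp)
      Mlist[[k]] <- comp_matmul(model, k, W)
      tr_est[k] <- sum(W * Slist[[k]]) / B
      quad[k] <- comp_quad(model, k, h$Py)
    }
    F_mat <- matrix(0, K + 1, K + 1)
    for (k in seq_len(K + 1)) {
      Tk <- projection_apply(model, h, Slist[[k]])  # P G_k z_b
      for (l in seq_len(K + 1))
        F_mat[l, k] <- F_mat[l, k] + 0.5 * sum(Mlist[[l]] * Tk) / B
    }
    F_mat <- (F_mat + t(F_mat)) / 2
  }
  grad <- -0.5 * (tr_est - quad)
  list(gradient = grad, fisher = F_mat, trace_est = tr_est)
}

#' Hutchinson stochastic trace estimate of a matrix
#'
#' tr(A) is estimated by mean_b z_b' A z_b. Rademacher probes are exact on
#' every draw when A is diagonal.
#'
#' @param A square matrix, or a function w -> A w.
#' @param n matrix order (required when `A` is a function).
#' @param probes a [probe_set()]; `kind` selects Rademacher or standard
#'   normal probes.
#' @return Scalar trace estimate.
#' @export
stochastic_trace <- function(A, probes, n = NULL) {
  stopifnot(inherits(probes, "probe_set"))
  apply_A <- if (is.function(A)) A else function(w) A %*% w
  n <- n %||% nrow(A)
  Zp <- with_local_seed(probes$seed, {
    if (probes$kind == "rademacher")
      matrix(sample(c(-1, 1), n * probes$count, replace = TRUE), n, probes$count)
    else matrix(stats::rnorm(n * probes$count), n, probes$count)
  })
  mean(colSums(Zp * apply_A(Zp)))
}
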