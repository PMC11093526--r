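## Method-of-moments estimators used as statistical-efficiency baselines for
## REML: Haseman-Elston regression, MINQUE with a working covariance prior,
## and an idealized LD-score regression fit on in-sample LD.

## Bordered MINQUE system in Rao's projected form. With working covariance
## Vt = sum_k G_k eta~_k + R sigma~_e2 and Pt the associated projection
## (annihilating X), solve
##   sum_l tr(Pt G_k Pt G_l) theta_l = y' Pt G_k Pt y,  k = 1..K+1,
## with G_{K+1} = R. When Vt is proportional to the identity this reduces to
## the Haseman-Elston normal equations on covariate-adjusted phenotypes, and
## evaluated at the REML estimates it is stationary there (iterated MINQUE
## converges to REML).
minque_system <- function(model, prior_vc) {
  h <- assemble_V(model, prior_vc)       # PD check on the prior
  P <- projection_dense(model, h)
  K <- model$K
  A <- vector("list", K + 1)
  for (k in seq_len(K)) A[[k]] <- P %*% dense_component(model, k)
  A[[K + 1]] <- P * rep(model$R_diag, each = model$n)
  Py <- drop(P %*% model$y)
  lhs <- matrix(0, K + 1, K + 1)
  rhs <- numeric(K + 1)
  for (k in seq_len(K + 1)) {
    rhs[k] <- comp_quad(model, k, Py)
    for (l in k:(K + 1)) {
      lhs[k, l] <- sum(A[[k]] * t(A[[l]]))
      lhs[l, k] <- lhs[k, l]
    }
  }
  list(lhs = lhs, rhs = rhs)
}

solve_moment_system <- function(model, sys, method) {
  if (rcond(sys$lhs) < 1e-12) {
    coll <- find_collinear_components(model)
    extra <- if (!is.null(coll))
      sprintf(" (components '%s' and '%s' are collinear)", coll[1], coll[2])
    else ""
    stop_vcpart(paste0("moment-estimator normal equations are singular", extra),
                "vcpart_collinearity_error")
  }
  est <- solve(sys$lhs, sys$rhs)
  structure(list(vc_hat = stats::setNames(est, c(model$labels, "residual")),
                 method = method),
            class = "moment_estimate")
}

#' @export
print.moment_estimate <- function(x, ...) {
  cat(sprintf("moment_estimate (%s):\n", x$method))
  print(data.frame(component = names(x$vc_hat), vc = as.numeric(x$vc_hat)),
        digits = 4)
  invisible(x)
}

#' Haseman-Elston regression variance-component estimates
#'
#' Method-of-moments estimator from the normal equations built on
#' tr(G_k G_l), tr(G_k) and N, applied to covariate-adjusted phenotypes
#' (equivalently, MINQUE with an identity working covariance). Estimates may
#' be negative.
#'
#' @param model a `mixed_model`.
#' @return A `moment_estimate` with `vc_hat` (components + residual).
#' @export
he_reg <- function(model) {
  prior <- c(rep(0, model$K), 1)
  sys <- minque_system(model, prior)
  solve_moment_system(model, sys, "he_reg")
}

#' MINQUE variance-component estimates with a working-covariance prior
#'
#' Minimum-norm quadratic unbiased estimation. The prior variance components
#' define the working covariance; statistical efficiency is best when their
#' ratios match the true ones, and with an identity-proportional prior the
#' estimator reduces exactly to Haseman-Elston regression. Evaluated at the
#' REML estimates the equations are stationary (the REML fixed point).
#'
#' @param model a `mixed_model`.
#' @param prior_vc numeric length K+1 giving the prior (eta, sigma_e2); must
#'   yield a positive-definite working covariance.
#' @return A `moment_estimate`.
#' @export
minque <- function(model, prior_vc) {
  sys <- minque_system(model, prior_vc)
  solve_moment_system(model, sys, "minque")
}

#' In-sample LD scores
#'
#' The LD score of SNP j is the sum over all SNPs of the squared genotype
#' correlations with SNP j, including the self-correlation of 1
#' (`mode = "observed"`). `mode = "expected_adjusted"` subtracts the finite
#' -sample bias 1/N for each of the other m-1 SNPs, so that independent SNPs
#' score about 1.
#'
#' @param Z a `std_geno` or a numeric genotype matrix (individuals x SNPs).
#' @param mode `"observed"` or `"expected_adjusted"`.
#' @return Data frame (snp_id, ld_score) with attribute `mode`.
#' @export
ld_scores <- function(Z, mode = c("observed", "expected_adjusted")) {
  mode <- match.arg(mode)
  if (inherits(Z, "std_geno")) {
    snp_ids <- Z$snp_ids; M <- Z$Z
  } else {
    M <- as.matrix(Z)
    snp_ids <- colnames(M) %||% sprintf("snp%05d", seq_len(ncol(M)))
  }
  if (ncol(M) < 2)
    stop_vcpart("at least 2 SNPs required for LD scores",
                "vcpart_parameter_error")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stop_vcpart(sprintf("zero-variance SNP column(s): %s",
                        paste(utils::head(snp_ids[sds == 0], 5), collapse = ", ")),
                "vcpart_monomorphic_error")
  C <- stats::cor(M)
  ell <- rowSums(C^2)
  if (mode == "expected_adjusted")
    ell <- ell - (ncol(M) - 1) / nrow(M)
  out <- data.frame(snp_id = snp_ids, ld_score = ell, stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

#' Single-SNP association z-scores
#'
#' s = Z' y_adj / sqrt(N sigma_p^2), where y_adj is the phenotype residual
#' after projecting out the covariates and sigma_p^2 = sum(y_adj^2)/N its
#' variance (denominator N). Under a pure-noise trait the s_j^2 average
#' about 1.
#'
#' @param Z a `std_geno` or standardized genotype matrix.
#' @param y phenotype vector.
#' @param X optional covariate matrix (intercept always included).
#' @return Data frame (snp_id, z) with attributes `n_gwas` and `sigma_p2`.
#' @export
gwas_z <- function(Z, y, X = NULL) {
  if (inherits(Z, "std_geno")) {
    snp_ids <- Z$snp_ids; M <- Z$Z
  } else {
    M <- as.matrix(Z)
    snp_ids <- colnames(M) %||% sprintf("snp%05d", seq_len(ncol(M)))
  }
  n <- length(y)
  Xf <- cbind(rep(1, n), if (!is.null(X)) as.matrix(X))
  y_adj <- stats::lm.fit(Xf, y)$residuals
  sigma_p2 <- sum(y_adj^2) / n
  s <- drop(crossprod(M, y_adj)) / sqrt(n * sigma_p2)
  out <- data.frame(snp_id = snp_ids, z = s, stringsAsFactors = FALSE)
  attr(out, "n_gwas") <- n
  attr(out, "sigma_p2") <- sigma_p2
  out
}

#' LD-score regression heritability fit
#'
#' Fits the diagonal-approximation model s_j ~ N(0, N l_j h2 / M + (1 - h2))
#' by iteratively reweighted least squares on the squared z-scores with
#' weights 1 / (2 (N l_j h2 / M + 1 - h2)^2), iterating the weights to
#' convergence. This is the idealized in-sample form (no intercept for
#' confounding, no reference-panel LD).
#'
#' @param z data frame from [gwas_z()] (or with columns snp_id, z and
#'   attribute `n_gwas`).
#' @param ld data frame from [ld_scores()].
#' @param m total number of SNPs M in the model (default: rows of `ld`).
#' @param n_gwas GWAS sample size (default: attribute of `z`).
#' @param tol IRLS convergence tolerance on h2.
#' @param max_iter maximum IRLS iterations.
#' @return List with `h2`, `n_iter`, `converged`.
#' @export
ldsc_fit <- function(z, ld, m = nrow(ld), n_gwas = attr(z, "n_gwas"),
                     tol = 1e-6, max_iter = 100L) {
  idx <- match(z$snp_id, ld$snp_id)
  if (anyNA(idx))
    stop_vcpart("z-score and LD-score tables do not align on snp_id",
                "vcpart_configuration_error")
  s2 <- z$z^2
  cj <- n_gwas * ld$ld_score[idx] / m - 1    # dvar/dh2
  h2 <- 0
  converged <- FALSE
  warned <- FALSE
  for (it in seq_len(max_iter)) {
    v <- 1 + h2 * cj
    if (any(v <= 0)) {
      if (!warned) {
        warning("non-positive fitted variance during IRLS; clamping",
                call. = FALSE)
        warned <- TRUE
      }
      v <- pmax(v, 1e-4)
    }
    w <- 1 / (2 * v^2)
    h2_new <- sum(w * cj * (s2 - 1)) / sum(w * cj^2)
    if (abs(h2_new - h2) < tol) {
      h2 <- h2_new
      converged <- TRUE
      break
    }
    h2 <- h2_new
  }
  list(h2 = h2, n_iter = it, converged = converged)
}
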