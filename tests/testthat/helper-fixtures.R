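## Shared fixture builders and dense-matrix oracles. Oracles are written
## directly from the model definition (explicit V, P) and never call the
## factorized code paths they check.

toy_dataset <- function(n = 60, K = 1, m_per = 40, ld_rho = 0, h2 = 0.5,
                        family_size = 0, n_traits = 1, seed = 1,
                        vc = NULL, maf_range = c(0.2, 0.5)) {
  geno <- simulate_genotypes(n, K * m_per, n_chrom = K, maf_range = maf_range,
                             ld_rho = ld_rho, family_size = family_size,
                             seed = seed)
  Z <- standardize(geno)
  gm <- chrom_group_map(geno)
  grms <- make_grms(Z, gm)
  vc <- vc %||% stats::setNames(rep(1, K), sprintf("chr%d", seq_len(K)))
  ph <- simulate_phenotypes(Z, gm, sim_scenario(vc, h2_target = h2,
                                                n_traits = n_traits,
                                                seed = seed + 7919))
  list(geno = geno, Z = Z, gm = gm, grms = grms, pheno = ph,
       y = stats::setNames(ph$trait_1, ph$id))
}

toy_model <- function(..., X = NULL) {
  d <- toy_dataset(...)
  mixed_model(d$y, d$grms, X = X)
}

## explicit dense V from a model and vc vector
dense_V <- function(model, vc) {
  K <- model$K
  V <- diag(vc[K + 1] * model$R_diag, model$n)
  for (k in seq_len(K))
    V <- V + vc[k] * matrix(model$Gstack[, k], model$n, model$n)
  V
}

## explicit dense projection P = Vi - Vi X (X'Vi X)^-1 X' Vi
dense_P <- function(model, vc) {
  V <- dense_V(model, vc)
  Vi <- solve(V)
  X <- model$X
  Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
}

## brute-force restricted log-likelihood from dense matrices
dense_reml_loglik <- function(model, vc) {
  V <- dense_V(model, vc)
  Vi <- solve(V)
  X <- model$X
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  -0.5 * (as.numeric(determinant(V)$modulus) +
          as.numeric(determinant(XtViX)$modulus) -
          as.numeric(determinant(t(X) %*% X)$modulus) +
          drop(t(model$y) %*% P %*% model$y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
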