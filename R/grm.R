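#' Standardize genotypes to zero mean and Hardy-Weinberg unit scale
#'
#' Missing entries are imputed to the column mean (2p), then column j is
#' transformed as (x - 2 p_j) / sqrt(2 p_j (1 - p_j)) with p_j the observed
#' allele frequency. Under Hardy-Weinberg equilibrium each column then has
#' unit variance, which keeps the mean diagonal of an all-SNP GRM near 1.
#'
#' @param geno a `genotype_matrix`.
#' @return A `std_geno`: list with `Z` (n x m numeric), `freqs` (observed
#'   allele frequencies used for scaling), `snp_ids`, `ind_ids`.
#' @export
standardize <- function(geno) {
  counts <- geno$counts
  p <- colMeans(counts, na.rm = TRUE) / 2
  mono <- which(p <= 0 | p >= 1 | !is.finite(p))
  if (length(mono))
    stop_vcpart(sprintf("monomorphic SNP(s): %s",
                        paste(utils::head(geno$snp_meta$id[mono], 5),
                              collapse = ", ")),
                "vcpart_monomorphic_error")
  Z <- sweep(counts, 2, 2 * p)
  if (anyNA(Z)) Z[is.na(Z)] <- 0          # mean imputation == 0 after centering
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  colnames(Z) <- geno$snp_meta$id
  rownames(Z) <- geno$ind_ids
  structure(list(Z = Z, freqs = p, snp_ids = geno$snp_meta$id,
                 ind_ids = geno$ind_ids),
            class = "std_geno")
}

#' Build a genomic relationship matrix from standardized genotypes
#'
#' G = Z_s Z_s' / |s| over the SNP subset s. Categories may overlap: a SNP in
#' two categories contributes fully to both GRMs.
#'
#' @param Z a `std_geno` from [standardize()].
#' @param snp_subset character vector of SNP ids (default: all SNPs).
#' @param label category name stored with the matrix.
#' @return A `grmatrix` (packed symmetric storage; see [write_grm()]).
#' @export
make_grm <- function(Z, snp_subset = NULL, label = "G") {
  stopifnot(inherits(Z, "std_geno"))
  if (is.null(snp_subset)) {
    idx <- seq_along(Z$snp_ids)
  } else {
    if (length(snp_subset) == 0)
      stop_vcpart(sprintf("category '%s' has no SNPs", label),
                  "vcpart_configuration_error")
    idx <- match(snp_subset, Z$snp_ids)
    if (anyNA(idx))
      stop_vcpart(sprintf("category '%s' references unknown SNPs: %s", label,
                          paste(utils::head(snp_subset[is.na(idx)], 5),
                                collapse = ", ")),
                  "vcpart_configuration_error")
  }
  G <- tcrossprod(Z$Z[, idx, drop = FALSE]) / length(idx)
  grmatrix(G, ids = Z$ind_ids, m_used = length(idx), label = label)
}

#' Construct a grmatrix from a dense symmetric matrix
#'
#' Stores the row-major lower triangle (length n(n+1)/2).
#'
#' @param G dense symmetric n x n matrix (or an already-packed numeric vector
#'   if `n` is given).
#' @param ids individual identifiers (length n).
#' @param m_used number of SNPs that contributed.
#' @param label category name.
#' @param n matrix order when `G` is a packed vector.
#' @return An object of class `grmatrix`.
#' @export
grmatrix <- function(G, ids, m_used, label = "G", n = NULL) {
  if (is.matrix(G)) {
    n <- nrow(G)
    packed <- pack_symmetric(G)
  } else {
    stopifnot(!is.null(n), length(G) == n * (n + 1) / 2)
    packed <- as.numeric(G)
  }
  stopifnot(length(ids) == n)
  structure(list(n = as.integer(n), ids = as.character(ids),
                 packed = packed, m_used = as.integer(m_used),
                 label = as.character(label)),
            class = "grmatrix")
}

#' @export
as.matrix.grmatrix <- function(x, ...) {
  M <- unpack_symmetric(x$packed, x$n)
  dimnames(M) <- list(x$ids, x$ids)
  M
}

#' @export
print.grmatrix <- function(x, ...) {
  d <- mean_diag_grm(x)
  cat(sprintf("grmatrix '%s': %d individuals, %d SNPs, mean diagonal %.3f\n",
              x$label, x$n, x$m_used, d))
  invisible(x)
}

## diagonal entries sit at packed positions i(i+1)/2
mean_diag_grm <- function(g) {
  i <- seq_len(g$n)
  mean(g$packed[i * (i + 1) / 2])
}

#' Build one GRM per SNP category
#'
#' @param Z a `std_geno`.
#' @param group_map data frame (snp_id, group); overlapping groups allowed.
#' @return Named list of `grmatrix`, one per category (order of first
#'   appearance in `group_map`).
#' @export
make_grms <- function(Z, group_map) {
  groups <- unique(group_map$group)
  out <- lapply(groups, function(g)
    make_grm(Z, group_map$snp_id[group_map$group == g], label = g))
  names(out) <- groups
  out
}
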