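#' Simulate diploid genotypes with tunable LD and optional full-sib families
#'
#' Generates allele counts for `n` individuals at `m` SNPs spread as evenly as
#' possible across `n_chrom` chromosomes. Each haplotype is produced from a
#' chromosome-wise first-order autoregressive latent Gaussian (correlation
#' `ld_rho` between adjacent SNPs) thresholded at the allele-frequency
#' quantile, so adjacent SNPs show tunable short-range linkage disequilibrium
#' while chromosomes are independent. Per-SNP minor-allele frequencies are
#' drawn uniformly from `maf_range` and stored in `snp_meta$allele_freq` as
#' the generator's targets.
#'
#' With `family_size >= 2`, individuals are grouped into full-sib families:
#' each family has two unobserved parents whose four haplotypes are generated
#' as above, and every sib inherits one whole-chromosome haplotype from each
#' parent (no within-chromosome recombination). This yields the relatedness
#' structure used for statistical-efficiency comparisons; the default
#' (`family_size = 0`) gives unrelated individuals.
#'
#' @param n number of individuals (>= 2).
#' @param m number of SNPs (>= `n_chrom`).
#' @param n_chrom number of chromosomes.
#' @param maf_range length-2 numeric within (0, 0.5], uniform sampling range
#'   of the minor-allele frequency.
#' @param ld_rho adjacent-SNP latent correlation in \[0, 1).
#' @param family_size 0 for unrelated individuals, otherwise the number of
#'   full sibs per family (`n` must be a multiple).
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @return A `genotype_matrix`: list with `counts` (n x m integer matrix of
#'   minor-allele counts in \{0,1,2\}), `snp_meta` (id, chrom, pos,
#'   allele_freq), `ind_ids`, and `fam_ids`.
#' @examples
#' g <- simulate_genotypes(50, 100, n_chrom = 5, ld_rho = 0.5, seed = 1)
#' dim(g$counts)
#' @export
simulate_genotypes <- function(n, m, n_chrom = 1L,
                               maf_range = c(0.01, 0.5),
                               ld_rho = 0,
                               family_size = 0L,
                               seed = NULL) {
  if (n < 2) stop_vcpart("n must be >= 2", "vcpart_parameter_error")
  if (m < n_chrom) stop_vcpart("m must be >= n_chrom", "vcpart_parameter_error")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_vcpart("maf_range must lie within (0, 0.5]", "vcpart_parameter_error")
  if (ld_rho < 0 || ld_rho >= 1)
    stop_vcpart("ld_rho must be in [0, 1)", "vcpart_parameter_error")
  if (family_size == 1 || (family_size > 0 && n %% family_size != 0))
    stop_vcpart("family_size must be 0 or >= 2 and divide n",
                "vcpart_parameter_error")

  run <- function() {
    per_chrom <- rep(m %/% n_chrom, n_chrom) +
      c(rep(1L, m %% n_chrom), rep(0L, n_chrom - m %% n_chrom))
    chrom <- rep(seq_len(n_chrom), per_chrom)
    pos <- unlist(lapply(per_chrom, function(k) seq_len(k) * 1000L),
                  use.names = FALSE)
    freq <- stats::runif(m, maf_range[1], maf_range[2])

    related <- family_size >= 2
    n_fam <- if (related) n %/% family_size else 0L
    ## haplotype rows: 2 per individual (unrelated) or 4 per family (parents)
    n_hap <- if (related) 4L * n_fam else 2L * n

    counts <- matrix(0L, n, m)
    col0 <- 0L
    for (c_i in seq_len(n_chrom)) {
      mc <- per_chrom[c_i]
      cols <- col0 + seq_len(mc)
      ## latent AR(1) across SNPs, independent across haplotypes
      X <- matrix(stats::rnorm(n_hap * mc), n_hap, mc)
      if (ld_rho > 0 && mc > 1) {
        s <- sqrt(1 - ld_rho^2)
        for (j in 2:mc) X[, j] <- ld_rho * X[, j - 1] + s * X[, j]
      }
      thr <- stats::qnorm(freq[cols])
      H <- X < rep(thr, each = n_hap)   # logical n_hap x mc
      if (!related) {
        counts[, cols] <- H[seq(1, 2 * n, by = 2), , drop = FALSE] +
          H[seq(2, 2 * n, by = 2), , drop = FALSE]
      } else {
        fam <- rep(seq_len(n_fam), each = family_size)
        pick_m <- sample(0:1, n, replace = TRUE)  # which maternal haplotype
        pick_p <- sample(0:1, n, replace = TRUE)
        im <- 4L * (fam - 1L) + 1L + pick_m
        ip <- 4L * (fam - 1L) + 3L + pick_p
        counts[, cols] <- H[im, , drop = FALSE] + H[ip, , drop = FALSE]
      }
      col0 <- col0 + mc
    }
    storage.mode(counts) <- "integer"

    ind_ids <- sprintf("ind%04d", seq_len(n))
    fam_ids <- if (related) sprintf("fam%03d", rep(seq_len(n %/% family_size),
                                                   each = family_size))
               else ind_ids
    genotype_matrix(
      counts = counts,
      snp_meta = data.frame(
        id = sprintf("snp%05d", seq_len(m)),
        chrom = chrom, pos = pos, allele_freq = freq,
        stringsAsFactors = FALSE
      ),
      ind_ids = ind_ids, fam_ids = fam_ids
    )
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Construct a genotype_matrix object
#'
#' Container for raw allele counts plus SNP metadata. Entries must be 0, 1, 2
#' or NA (missing).
#'
#' @param counts n x m integer matrix of allele counts.
#' @param snp_meta data frame with columns id, chrom, pos, allele_freq.
#' @param ind_ids unique individual identifiers.
#' @param fam_ids family identifiers (defaults to `ind_ids`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts, snp_meta, ind_ids, fam_ids = ind_ids) {
  counts <- as.matrix(counts)
  bad <- !is.na(counts) & !(counts %in% 0:2)
  if (any(bad))
    stop_vcpart("genotype counts must be 0, 1, 2 or NA", "vcpart_parameter_error")
  if (nrow(snp_meta) != ncol(counts))
    stop_vcpart("snp_meta rows must match genotype columns",
                "vcpart_parameter_error")
  if (anyDuplicated(ind_ids))
    stop_vcpart("individual ids must be unique", "vcpart_parameter_error")
  if (length(ind_ids) != nrow(counts))
    stop_vcpart("ind_ids length must match genotype rows",
                "vcpart_parameter_error")
  structure(list(counts = counts, snp_meta = snp_meta,
                 ind_ids = as.character(ind_ids),
                 fam_ids = as.character(fam_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$snp_meta$chrom))))
  invisible(x)
}

#' Drop SNPs below a minor-allele-frequency threshold
#'
#' Observed allele frequencies are computed from the counts (missing entries
#' ignored); SNPs with min(p, 1-p) below the threshold are removed.
#'
#' @param geno a `genotype_matrix`.
#' @param maf_threshold minimum minor-allele frequency to retain.
#' @return The filtered `genotype_matrix`.
#' @export
filter_maf <- function(geno, maf_threshold = 0.01) {
  p <- colMeans(geno$counts, na.rm = TRUE) / 2
  keep <- pmin(p, 1 - p) >= maf_threshold
  genotype_matrix(geno$counts[, keep, drop = FALSE],
                  geno$snp_meta[keep, , drop = FALSE],
                  geno$ind_ids, geno$fam_ids)
}

#' Define a phenotype-simulation scenario
#'
#' @param vc_per_group named numeric: non-negative variance component per SNP
#'   group (relative scale).
#' @param h2_target heritability in \[0, 1): expected share of phenotypic
#'   variance explained by all genetic components together.
#' @param n_traits number of independent replicate traits.
#' @param seed integer seed.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(vc_per_group, h2_target = 0.5, n_traits = 1L,
                         seed = NULL) {
  if (any(vc_per_group < 0))
    stop_vcpart("variance components must be non-negative",
                "vcpart_parameter_error")
  if (h2_target < 0 || h2_target >= 1)
    stop_vcpart("h2_target must be in [0, 1)", "vcpart_parameter_error")
  if (sum(vc_per_group) == 0 && h2_target > 0)
    stop_vcpart("sum of VCs must be > 0 unless h2_target = 0",
                "vcpart_configuration_error")
  if (n_traits < 1)
    stop_vcpart("n_traits must be >= 1", "vcpart_parameter_error")
  if (is.null(names(vc_per_group)))
    names(vc_per_group) <- sprintf("g%d", seq_along(vc_per_group))
  structure(list(vc_per_group = vc_per_group, h2_target = h2_target,
                 n_traits = as.integer(n_traits), seed = seed),
            class = "sim_scenario")
}

#' Simulate phenotypes under per-category variance components
#'
#' For each trait, SNP effects are drawn independently per group g as
#' Normal(0, vc_g / m_g) where m_g is the number of SNPs in group g (a SNP in
#' several groups receives the sum of its per-group effects), genetic values
#' are Z alpha, and the residual variance is set so that the heritability
#' Var(g)/(Var(g)+Var(e)) equals `h2_target` in expectation (no per-replicate
#' rescaling). With all VCs zero and `h2_target = 0`, phenotypes are pure
#' unit-variance residual noise.
#'
#' @param Z standardized genotypes (`std_geno` from [standardize()], or a
#'   numeric matrix with SNP ids as column names).
#' @param group_map data frame (snp_id, group) mapping SNPs to groups;
#'   overlapping groups allowed.
#' @param scenario a [sim_scenario()].
#' @return Data frame with column `id` and one column per trait
#'   (`trait_1`, ...). Attributes `sigma_e2` (residual variance used) and
#'   `genetic_values` (n x n_traits matrix) support variance accounting.
#' @export
simulate_phenotypes <- function(Z, group_map, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (inherits(Z, "std_geno")) {
    ids <- Z$ind_ids; snp_ids <- Z$snp_ids; Z <- Z$Z
  } else {
    Z <- as.matrix(Z)
    snp_ids <- colnames(Z) %||% sprintf("snp%05d", seq_len(ncol(Z)))
    ids <- rownames(Z) %||% sprintf("ind%04d", seq_len(nrow(Z)))
  }
  vc <- scenario$vc_per_group
  groups <- names(vc)
  idx_by_group <- lapply(groups, function(g)
    match(group_map$snp_id[group_map$group == g], snp_ids))
  names(idx_by_group) <- groups
  for (g in groups) {
    idx <- idx_by_group[[g]]
    if (anyNA(idx))
      stop_vcpart(sprintf("group '%s' references SNPs absent from Z", g),
                  "vcpart_configuration_error")
    if (length(idx) == 0 && vc[[g]] > 0)
      stop_vcpart(sprintf("group '%s' has a positive VC but no SNPs", g),
                  "vcpart_configuration_error")
  }
  mapped <- unique(unlist(idx_by_group))
  if (sum(vc) > 0 && length(setdiff(seq_len(ncol(Z)), mapped)) == ncol(Z))
    stop_vcpart("group_map covers none of Z's SNPs", "vcpart_configuration_error")

  total_vc <- sum(vc)
  h2 <- scenario$h2_target
  sigma_e2 <- if (total_vc == 0) 1 else total_vc * (1 - h2) / h2
  n <- nrow(Z); Tn <- scenario$n_traits

  run <- function() {
    gval <- matrix(0, n, Tn)
    for (t in seq_len(Tn)) {
      alpha <- numeric(ncol(Z))
      for (g in groups) {
        idx <- idx_by_group[[g]]
        if (length(idx) == 0 || vc[[g]] == 0) next
        alpha[idx] <- alpha[idx] +
          stats::rnorm(length(idx), 0, sqrt(vc[[g]] / length(idx)))
      }
      gval[, t] <- if (total_vc > 0) Z %*% alpha else 0
    }
    y <- gval + matrix(stats::rnorm(n * Tn, 0, sqrt(sigma_e2)), n, Tn)
    colnames(y) <- sprintf("trait_%d", seq_len(Tn))
    out <- data.frame(id = ids, y, stringsAsFactors = FALSE)
    attr(out, "sigma_e2") <- sigma_e2
    attr(out, "genetic_values") <- gval
    out
  }
  if (is.null(scenario$seed)) run() else with_local_seed(scenario$seed, run())
}

#' Benchmark scenario presets for chromosome-partitioning simulations
#'
#' Returns the per-group variance components of the benchmark designs:
#' `"s1"` — VC 1 for chromosomes 1-15 and 0 for 16-30; `"s2"` — VC 1 for all
#' 30 chromosomes; `"s3"` — VC 1 for chromosomes 1-15 and 2 for 16-30;
#' `"split14"` — two SNP categories `setA`/`setB` with VCs 1 and 4.
#'
#' @param name one of `"s1"`, `"s2"`, `"s3"`, `"split14"`.
#' @param n_chrom number of chromosomes for the chromosome scenarios.
#' @return Named numeric vector of variance components, group label = chrom
#'   label (`chr1`...) or `setA`/`setB`.
#' @export
scenario_preset <- function(name = c("s1", "s2", "s3", "split14"),
                            n_chrom = 30L) {
  name <- match.arg(name)
  if (name == "split14") return(c(setA = 1, setB = 4))
  half <- n_chrom %/% 2
  vc <- switch(name,
    s1 = c(rep(1, half), rep(0, n_chrom - half)),
    s2 = rep(1, n_chrom),
    s3 = c(rep(1, half), rep(2, n_chrom - half)))
  names(vc) <- sprintf("chr%d", seq_len(n_chrom))
  vc
}

#' Group map assigning every SNP to its chromosome
#'
#' @param geno a `genotype_matrix`.
#' @return Data frame (snp_id, group) with group labels `chr<k>`.
#' @export
chrom_group_map <- function(geno) {
  data.frame(snp_id = geno$snp_meta$id,
             group = sprintf("chr%d", geno$snp_meta$chrom),
             stringsAsFactors = FALSE)
}
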