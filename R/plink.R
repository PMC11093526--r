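## PLINK .bed/.bim/.fam input/output.
##
## .bed is SNP-major: magic bytes 0x6C 0x1B 0x01, then per SNP ceiling(n/4)
## bytes, 2 bits per individual (low bits first). Two-bit codes: 00 =
## homozygous A1, 01 = missing, 10 = heterozygous, 11 = homozygous A2.
## Counts are of the A1 allele, so 00 -> 2, 10 -> 1, 11 -> 0.

#' Write a genotype_matrix as a PLINK .bed/.bim/.fam fileset
#'
#' @param geno a `genotype_matrix`.
#' @param prefix output path prefix (writes `<prefix>.bed`, `.bim`, `.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  n <- nrow(geno$counts); m <- ncol(geno$counts)
  meta <- geno$snp_meta
  utils::write.table(
    data.frame(meta$chrom, meta$id, 0L, meta$pos, "A", "B"),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(geno$fam_ids, geno$ind_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  code <- geno$counts            # allele count -> 2-bit code
  code[is.na(code)] <- -1L
  map <- c(`-1` = 1L, `0` = 3L, `1` = 2L, `2` = 0L)
  code <- matrix(map[as.character(code)], n, m)
  n_pad <- 4L * ((n + 3L) %/% 4L)
  if (n_pad > n) code <- rbind(code, matrix(0L, n_pad - n, m))
  dim(code) <- c(4L, (n_pad %/% 4L) * m)
  bytes <- as.raw(code[1, ] + 4L * code[2, ] + 16L * code[3, ] + 64L * code[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

#' Read a PLINK .bed/.bim/.fam fileset
#'
#' A1 alleles are counted (0/1/2); PLINK missing code becomes NA.
#' `snp_meta$allele_freq` holds the observed A1 frequency.
#'
#' @param prefix path prefix of the fileset.
#' @return A `genotype_matrix`.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "A1", "A2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", rep(NA, 4)))
  n <- nrow(fam); m <- nrow(bim)
  bed_path <- paste0(prefix, ".bed")
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) ||
      raw[3] != as.raw(0x01))
    stop_vcpart(sprintf("'%s' is not a SNP-major PLINK .bed file", bed_path),
                "vcpart_format_error")
  bps <- (n + 3L) %/% 4L                 # bytes per SNP
  if (length(raw) - 3L != bps * m)
    stop_vcpart(sprintf(".bed payload: expected %d bytes, found %d",
                        bps * m, length(raw) - 3L), "vcpart_format_error")
  b <- as.integer(raw[-(1:3)])
  codes <- matrix(0L, 4L * bps, m)
  for (k in 0:3)
    codes[seq(k + 1L, by = 4L, length.out = bps), ] <-
      matrix(bitwAnd(bitwShiftR(b, 2L * k), 3L), bps, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  counts <- matrix(c(2L, NA_integer_, 1L, 0L)[codes + 1L], n, m)
  p <- colMeans(counts, na.rm = TRUE) / 2
  genotype_matrix(
    counts,
    data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
               allele_freq = p, stringsAsFactors = FALSE),
    ind_ids = fam$V2, fam_ids = fam$V1)
}

#' Write phenotype and SNP-category tables as CSV
#'
#' @param pheno data frame from [simulate_phenotypes()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pheno_csv <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pheno_csv
#' @param group_map data frame (snp_id, group).
#' @export
write_group_csv <- function(group_map, path) {
  utils::write.csv(group_map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SNP-category CSV (columns snp_id, group)
#'
#' @param path CSV path.
#' @return Data frame (snp_id, group).
#' @export
read_group_csv <- function(path) {
  gm <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "group") %in% names(gm)))
    stop_vcpart("category file needs columns snp_id, group",
                "vcpart_format_error")
  gm
}
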