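## Packed binary GRM format ("MPHG"), little-endian:
##   magic "MPHG" (4 bytes) | version uint32 = 1 | n uint32 | m_used uint64 |
##   label (uint16 length + UTF-8) | n x (uint16 length + UTF-8 id) |
##   n(n+1)/2 float64, row-major lower triangle.
## Row i (1-based) starts at packed offset i(i-1)/2 and has length i, which
## makes contiguous row-block streaming trivial.

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                       endian = "little")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4,
                                       endian = "little")

#' Write a GRM in the packed binary format
#'
#' @param g a `grmatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_grm()] for the format definition and streamed access.
#' @export
write_grm <- function(g, path) {
  stopifnot(inherits(g, "grmatrix"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MPHG"), con)
  write_u32(con, 1L)
  write_u32(con, g$n)
  write_u32(con, g$m_used); write_u32(con, 0L)   # uint64, high word 0
  lab <- charToRaw(enc2utf8(g$label))
  write_u16(con, length(lab)); writeBin(lab, con)
  for (id in g$ids) {
    r <- charToRaw(enc2utf8(id))
    write_u16(con, length(r)); writeBin(r, con)
  }
  writeBin(g$packed, con, size = 8, endian = "little")
  invisible(path)
}

read_u16 <- function(con) readBin(con, "integer", size = 2, signed = FALSE,
                                  endian = "little")
read_u32 <- function(con) readBin(con, "integer", size = 4, endian = "little")

read_grm_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (length(magic) < 4 || rawToChar(magic) != "MPHG")
    stop_vcpart(sprintf("'%s': bad magic, not an MPHG GRM file", path),
                "vcpart_format_error")
  version <- read_u32(con)
  if (!identical(version, 1L))
    stop_vcpart(sprintf("'%s': unsupported MPHG version %d", path, version),
                "vcpart_format_error")
  n <- read_u32(con)
  m_lo <- read_u32(con); m_hi <- read_u32(con)
  m_used <- m_lo + m_hi * 2^32
  lab_len <- read_u16(con)
  label <- rawToChar(readBin(con, "raw", lab_len))
  ids <- character(n)
  for (i in seq_len(n)) {
    l <- read_u16(con)
    ids[i] <- rawToChar(readBin(con, "raw", l))
  }
  offset <- seek(con)
  expected <- offset + 8 * n * (n + 1) / 2
  actual <- file.size(path)
  if (actual != expected)
    stop_vcpart(sprintf("'%s': truncated payload, expected %d bytes, found %d",
                        path, expected, actual), "vcpart_format_error")
  list(path = path, n = n, m_used = m_used, label = label, ids = ids,
       data_offset = offset)
}

#' Read a GRM from the packed binary format
#'
#' `mode = "full"` materializes the whole matrix as a `grmatrix`.
#' `mode = "streamed"` returns a lightweight `grm_stream` handle exposing
#' row-block access ([grm_stream_rows()]) and symmetric matrix products
#' ([grm_matmul()]) without loading the packed payload into memory, which is
#' what the REML memory-saving mode uses.
#'
#' @param path file path.
#' @param mode `"full"` or `"streamed"`.
#' @return A `grmatrix` or a `grm_stream`.
#' @export
read_grm <- function(path, mode = c("full", "streamed")) {
  mode <- match.arg(mode)
  h <- read_grm_header(path)
  if (mode == "streamed")
    return(structure(h, class = "grm_stream"))
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, h$data_offset)
  packed <- readBin(con, "double", n = h$n * (h$n + 1) / 2, size = 8,
                    endian = "little")
  grmatrix(packed, ids = h$ids, m_used = h$m_used, label = h$label, n = h$n)
}

#' @export
print.grm_stream <- function(x, ...) {
  cat(sprintf("grm_stream '%s': %d individuals, %d SNPs (%s)\n",
              x$label, x$n, x$m_used, x$path))
  invisible(x)
}

#' Read a block of packed GRM rows from a streamed handle
#'
#' Returns rows `i1:i2` of the lower triangle as a dense (i2-i1+1) x i2
#' matrix whose entries above the diagonal are zero.
#'
#' @param h a `grm_stream`.
#' @param i1,i2 first and last row (1-based, i1 <= i2 <= n).
#' @return Numeric matrix of the block rows.
#' @export
grm_stream_rows <- function(h, i1, i2) {
  stopifnot(inherits(h, "grm_stream"), i1 >= 1, i2 >= i1, i2 <= h$n)
  off <- (i1 - 1) * i1 / 2                 # packed entries before row i1
  len <- i2 * (i2 + 1) / 2 - off
  con <- file(h$path, "rb")
  on.exit(close(con))
  seek(con, h$data_offset + 8 * off)
  v <- readBin(con, "double", n = len, size = 8, endian = "little")
  nr <- i2 - i1 + 1
  B <- matrix(0, nr, i2)
  pos <- 0L
  for (i in i1:i2) {
    B[i - i1 + 1, seq_len(i)] <- v[pos + seq_len(i)]
    pos <- pos + i
  }
  B
}

## Symmetric matrix product G %*% W for dense grmatrix or streamed handle.
grm_matmul_dense <- function(G, W) G %*% W

#' Multiply a (possibly streamed) GRM by a dense matrix
#'
#' Computes G W using only lower-triangle row blocks, so a `grm_stream` never
#' materializes the full matrix.
#'
#' @param g a `grmatrix` or `grm_stream`.
#' @param W numeric matrix (n rows) or vector.
#' @param block_rows rows per streamed block.
#' @return Numeric matrix G W.
#' @export
grm_matmul <- function(g, W, block_rows = 512L) {
  W <- as.matrix(W)
  if (inherits(g, "grmatrix"))
    return(unpack_symmetric(g$packed, g$n) %*% W)
  stopifnot(inherits(g, "grm_stream"), nrow(W) == g$n)
  n <- g$n
  out <- matrix(0, n, ncol(W))
  i1 <- 1L
  while (i1 <= n) {
    i2 <- min(i1 + block_rows - 1L, n)
    B <- grm_stream_rows(g, i1, i2)            # (i2-i1+1) x i2, lower rows
    rows <- i1:i2
    out[rows, ] <- out[rows, , drop = FALSE] + B %*% W[seq_len(i2), , drop = FALSE]
    out[seq_len(i2), ] <- out[seq_len(i2), , drop = FALSE] +
      crossprod(B, W[rows, , drop = FALSE])
    d <- B[cbind(seq_len(i2 - i1 + 1L), rows)]  # diagonal counted twice
    out[rows, ] <- out[rows, , drop = FALSE] - d * W[rows, , drop = FALSE]
    i1 <- i2 + 1L
  }
  out
}

## Accumulate eta * G into dense V (streamed-aware).
grm_add_into <- function(V, g, eta, block_rows = 512L) {
  if (inherits(g, "grmatrix"))
    return(V + eta * unpack_symmetric(g$packed, g$n))
  n <- g$n
  i1 <- 1L
  while (i1 <= n) {
    i2 <- min(i1 + block_rows - 1L, n)
    B <- grm_stream_rows(g, i1, i2)
    rows <- i1:i2
    V[rows, seq_len(i2)] <- V[rows, seq_len(i2), drop = FALSE] + eta * B
    ## mirror strictly-lower entries to the upper triangle
    Bl <- B
    Bl[cbind(seq_len(i2 - i1 + 1L), rows)] <- 0
    V[seq_len(i2), rows] <- V[seq_len(i2), rows, drop = FALSE] + eta * t(Bl)
    i1 <- i2 + 1L
  }
  V
}

grm_n <- function(g) g$n
grm_ids <- function(g) g$ids
grm_label <- function(g) g$label

grm_mean_diag <- function(g) {
  if (inherits(g, "grmatrix")) return(mean_diag_grm(g))
  i <- seq_len(g$n)
  con <- file(g$path, "rb")
  on.exit(close(con))
  d <- numeric(g$n)
  for (k in i) {
    seek(con, g$data_offset + 8 * (k * (k + 1) / 2 - 1))
    d[k] <- readBin(con, "double", 1, size = 8, endian = "little")
  }
  mean(d)
}
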