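`%||%` <- function(a, b) if (is.null(a)) b else a

## Row-major lower triangle of a symmetric matrix == column-major upper
## triangle (incl. diagonal), which is what upper.tri() indexing yields.
pack_symmetric <- function(M) {
  M[upper.tri(M, diag = TRUE)]
}

unpack_symmetric <- function(packed, n) {
  stopifnot(length(packed) == n * (n + 1L) / 2L)
  M <- matrix(0, n, n)
  M[upper.tri(M, diag = TRUE)] <- packed
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

## Run expr with a private RNG state; global .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic child seeds below 2^31, decorrelated across streams.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483647
}

stop_vcpart <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "vcpart_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

msg_info <- function(...) message(sprintf(...))
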