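# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0)
    stopf("'%s' must be positive", name)
  invisible(x)
}

#' Derive a child RNG seed from a base seed
#'
#' Deterministically maps a user seed plus a stream label to a 31-bit
#' integer so independent noise sources (cardiac jitter, interference,
#' sensor noise, empty-room realization) draw from distinct streams.
#'
#' @param seed base integer seed.
#' @param stream small integer stream index.
#' @return an integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 104729 * as.double(stream)) %% 2147483629)
}

# largest canonical angle (degrees) between the column spaces of two matrices
subspace_angle_deg <- function(U, V) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (ncol(U) == 0L || ncol(V) == 0L) return(0)
  qu <- qr.Q(qr(U)); qv <- qr.Q(qr(V))
  s <- svd(crossprod(qu, qv))$d
  s <- pmin(pmax(s, -1), 1)
  max(acos(s)) * 180 / pi
}
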