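#' Convert a linear magnitude to decibels
#'
#' Uses the amplitude convention `dB(x) = 20 * log10(x)`, so doubling a
#' magnitude adds about 6.0206 dB.
#'
#' @param x Non-negative linear magnitude(s).
#' @return Value(s) in dB. `db(0)` is `-Inf`.
#' @export
#' @examples
#' db(10)        # 20
#' db(2) - db(1) # ~6.0206
db <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("magnitudes must be non-negative")
  20 * log10(x)
}

# Deterministic per-unit seed derivation from a master seed.  Linear
# congruential step modulo the Mersenne prime 2^31 - 1; keeps every derived
# seed a valid 32-bit R integer and distinct streams for distinct indices.
derive_seed <- function(master_seed, index) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m) + 1
  for (k in seq_len(2)) s <- (48271 * (s + as.numeric(index) * 16807)) %% m
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bbb <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
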