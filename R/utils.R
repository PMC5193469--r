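#' Round half away from zero
#'
#' Rounds `x` to `digits` decimal places with ties going up (the convention
#' used for printed report percentages), unlike base `round()`'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(c(0.5, 1.5, 75.757), 0)
#' @export
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## stop() with a consistent prefix-free message and no call noise
abort <- function(...) stop(sprintf(...), call. = FALSE)

checkCounts <- function(n, what) {
  if (length(n) == 0) abort("%s: no counts supplied", what)
  if (any(is.na(n)) || any(n < 0) || any(n != floor(n)))
    abort("%s: counts must be non-negative integers", what)
  invisible(as.integer(n))
}

## derive a child RNG seed from a base seed without exceeding .Machine 32-bit
childSeed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 16807) %% 2147483647
}
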