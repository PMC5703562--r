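# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; screening tables in the
#' telepathology literature round percentages half away from zero
#' (46.67 -> 47, 90.48 -> 90). This helper implements that convention.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(46.67, 63.33, 66.67, 90.48, 0.5, -0.5))
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic sub-seed from a base seed and a set of coordinates.
# Keeps every derived seed in [0, 2^31): R's set.seed() takes 32-bit ints.
mix_seed <- function(seed, ...) {
  vals <- vapply(list(...), function(v) {
    as.double(as.integer(round(v * 8)) %% 65536L)
  }, numeric(1))
  h <- as.double(seed %% 2147483647)
  for (v in c(vals, 0)) {
    h <- (h * 69069 + v + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_fixed_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
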