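# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base [round()] rounds half to even; printed clinical percentages use
#' conventional half-up rounding (93.75 -> 93.8), so aggregation code uses
#' this helper for every reported figure.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stream RNG seed from a master seed and labels
#'
#' Counter-based substream derivation: the master seed and an arbitrary
#' sequence of labels (group names, patient indices, stage names) are folded
#' into a 31-bit integer by a multiplicative string hash, so that every
#' (seed, labels) pair maps to a fixed, platform-independent seed usable
#' with [set.seed()]. Changing any label or the master seed decorrelates the
#' stream; the same inputs always give the same stream.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
rng_substream <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (lab in list(...)) {
    for (code in utf8ToInt(paste0("|", as.character(lab)))) {
      h <- (h * 31 + code) %% m
    }
  }
  h <- (h * 48271) %% m  # final scramble (MINSTD multiplier)
  as.integer(h + 1)
}

# stop() with a consistent prefix so stage failures are attributable
abort <- function(..., class = "crcatlas_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) abort(...)
  invisible(TRUE)
}
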