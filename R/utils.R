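#' Round half away from zero
#'
#' Commercial rounding used for the per-chromosome spacing and density
#' figures: halves round away from zero rather than to the nearest even
#' integer as [base::round()] does.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_away(c(0.5, 1.5, 2.4, -0.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a stage seed from the pipeline seed
#'
#' All stochastic stages draw their randomness from one top-level integer
#' seed. Each stage's own seed is derived deterministically from the pipeline
#' seed and the stage label, so any stage can be reproduced in isolation.
#' The derivation is a small multiplicative hash of the label's UTF-8 bytes
#' folded into the seed, reduced modulo 2^31 - 1.
#'
#' @param seed integer pipeline seed.
#' @param label character stage label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(label)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# internal: stop with a consistent message prefix
abort_slaf <- function(...) {
  stop(paste0(...), call. = FALSE)
}

# internal: check a scalar probability
check_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1 || !lo_ok || !hi_ok) {
    abort_slaf(name, " must be a single number in ",
               if (open_left) "(" else "[", "0,1",
               if (open_right) ")" else "]")
  }
  invisible(x)
}
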