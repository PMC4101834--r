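# internal helpers shared across modules

#' Round half away from zero
#'
#' Commercial rounding used wherever expected (fractional) person or event
#' counts are presented as integers: 196.95 -> 197, 39.5 -> 40. Base
#' `round()` rounds half to even, which is not the convention used for the
#' reported counts.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

check_prob <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1,
          sprintf("'%s' must be a single probability in [0, 1]", name))
  invisible(x)
}

check_nonneg <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0,
          sprintf("'%s' must be a single non-negative number", name))
  invisible(x)
}
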