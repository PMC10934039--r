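#' Round half away from zero
#'
#' Commercial-rounding convention used for all reported percentages:
#' ties go up (2.5 -> 3), unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(4.8128 * 10, 1)
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared tolerance for time-grid boundary comparisons (s)
.t_eps <- 1e-9
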