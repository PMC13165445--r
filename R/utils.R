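#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up in magnitude), used for all
#' reported percentages, picogram values and megabase counts so that
#' rendered tables match conventional hand-rounding rather than the
#' round-half-even rule of [base::round()]. A small guard compensates for
#' binary floating-point representation of decimal inputs.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return \code{x} rounded half-up at \code{digits} decimals.
#' @examples
#' round_half_up(2.675, 2)   # 2.68, where round() gives 2.67
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
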