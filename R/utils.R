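#' Round half away from zero
#'
#' Display rounding for scoring reports. R's [round()] uses round-half-to-even
#' (banker's rounding); scoring matrices in this field are conventionally
#' printed with halves rounded up, so the display path uses this explicit rule.
#' All internal arithmetic stays at full double precision; this function is for
#' rendering only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded to `digits` places, halves away from zero.
#' @examples
#' round_half_up(2.345, 2) # 2.35
#' round_half_up(0.5, 0)   # 1
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by one ulp so values stored just under x.xx5 still round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_pocmcda <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
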