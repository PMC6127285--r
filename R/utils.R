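#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed clinical summaries use
#' conventional half-up rounding (58.6206 -> 58.62 at 2 dp).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
  invisible(TRUE)
}
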