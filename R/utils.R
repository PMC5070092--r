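#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), the convention used in
#' the package's reports, as opposed to base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(2.345, 2)  # 2.35
#' @export
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# fixed decimal formatting for result writers; NA -> "NA"
fmtNum <- function(x, digits = 6) {
    out <- formatC(x, format = "f", digits = digits)
    out[is.na(x)] <- "NA"
    out
}

# stop() without the call, for cleaner user-facing errors
abort <- function(...) stop(..., call. = FALSE)

# midpoint of a GRanges interval (integer floor)
grMidpoint <- function(gr) {
    as.integer(floor((start(gr) + end(gr)) / 2))
}
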