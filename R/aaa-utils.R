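#' @keywords internal
#' @useDynLib wheatmoe, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Feature order used everywhere: 6 dynamic remote-sensing/biophysical variables,
# 2 meteorological drivers, 2 static county covariates.
FEATURES <- c("NDVI", "EVI", "NIRv", "Red", "LAI", "Fpar", "RHum", "Rad", "DEM", "SoC")
STATIC_FEATURES <- c("DEM", "SoC")
SEASON_LENGTH <- 10L
# Month 1 = September, month 10 = June of the harvest year.
MONTH_LABELS <- c("Sep", "Oct", "Nov", "Dec", "Jan", "Feb", "Mar", "Apr", "May", "Jun")

abort <- function(msg, class) {
  stop(structure(class = c(class, "wheatmoe_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed agreement statistics use the
#' conventional half-away-from-zero rule, so 90.65 -> 90.7.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) abort(sprintf("non-finite values in %s", what), "wheatmoe_nonfinite")
  invisible(x)
}
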