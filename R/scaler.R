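# Min-max scaling fitted on the training split only. Features are mapped into
# [0, 1] per feature over the training samples; validation/test samples are
# transformed with the training parameters and may leave [0, 1]. The yield
# label can optionally be scaled the same way, with an exact inverse for
# reporting metrics in kg/ha.

#' Fit a min-max scaler on training samples
#'
#' @param train list of [season_tensor()] (training split only).
#' @param scale_target also fit min/max for the yield label?
#' @return object of class `minmax_scaler`; records the keys of the samples it
#'   saw (`seen_keys`) so leakage can be audited.
#' @export
fit_scaler <- function(train, scale_target = TRUE) {
  if (length(train) == 0) abort("cannot fit scaler on empty training set", "wheatmoe_invalid_input")
  allx <- do.call(rbind, lapply(train, `[[`, "x"))
  fmin <- apply(allx, 2, min)
  fmax <- apply(allx, 2, max)
  out <- list(feature_min = fmin, feature_max = fmax, fitted = TRUE,
              scale_target = scale_target, seen_keys = dataset_keys(train))
  if (scale_target) {
    yy <- dataset_yields(train)
    if (all(is.na(yy))) abort("scale_target = TRUE but no yield labels", "wheatmoe_invalid_input")
    out$y_min <- min(yy, na.rm = TRUE)
    out$y_max <- max(yy, na.rm = TRUE)
  }
  structure(out, class = "minmax_scaler")
}

scale_col <- function(x, mn, mx) {
  # constant training column maps to 0 by convention
  if (mx - mn <= 0) return(rep(0, length(x)))
  (x - mn) / (mx - mn)
}

#' Apply a fitted scaler to samples
#'
#' @param scaler a fitted [fit_scaler()] object.
#' @param samples list of [season_tensor()] (any split).
#' @return list of scaled `season_tensor`s (yields scaled too when the scaler
#'   was fitted with `scale_target = TRUE`).
#' @export
apply_scaler <- function(scaler, samples) {
  if (!inherits(scaler, "minmax_scaler") || !isTRUE(scaler$fitted))
    abort("scaler not fitted", "wheatmoe_not_fitted")
  lapply(samples, function(s) {
    x <- s$x
    for (j in seq_along(FEATURES))
      x[, j] <- scale_col(x[, j], scaler$feature_min[j], scaler$feature_max[j])
    y <- s$y
    if (scaler$scale_target && !is.na(y)) y <- scale_target(scaler, y)
    season_tensor(s$county_id, s$year, x, y)
  })
}

#' Scale / inverse-scale yield values
#'
#' @param scaler fitted scaler with `scale_target = TRUE`.
#' @param y yield values (kg/ha for `scale_target`, scaled units for
#'   `inverse_target`).
#' @return transformed values.
#' @export
scale_target <- function(scaler, y) {
  if (is.null(scaler$y_min)) abort("scaler has no target parameters", "wheatmoe_not_fitted")
  if (scaler$y_max - scaler$y_min <= 0) return(rep(0, length(y)))
  (y - scaler$y_min) / (scaler$y_max - scaler$y_min)
}

#' @rdname scale_target
#' @export
inverse_target <- function(scaler, y) {
  if (is.null(scaler$y_min)) abort("scaler has no target parameters", "wheatmoe_not_fitted")
  y * (scaler$y_max - scaler$y_min) + scaler$y_min
}

#' Serialize scaler parameters to JSON (and back)
#'
#' @param scaler fitted scaler.
#' @param path file path.
#' @return `read_scaler` returns the scaler; `write_scaler` the path, invisibly.
#' @export
write_scaler <- function(scaler, path) {
  obj <- unclass(scaler)
  obj$seen_keys <- NULL
  # named vectors serialize as bare arrays; lists keep their names
  obj$feature_min <- as.list(obj$feature_min)
  obj$feature_max <- as.list(obj$feature_max)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$feature_min <- unlist(obj$feature_min)[FEATURES]
  obj$feature_max <- unlist(obj$feature_max)[FEATURES]
  obj$seen_keys <- character(0)
  structure(obj, class = "minmax_scaler")
}
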