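# Season tensors: one county-year sample is a 10 (months, Sep -> Jun) x 10
# (features) matrix plus a yield label in kg/ha. Month 1 is September of the
# sowing year; the harvest year (the June side) labels the season.

#' Construct a season tensor
#'
#' @param county_id character scalar.
#' @param year integer harvest year.
#' @param x numeric matrix, months x features, with columns in the canonical
#'   order `NDVI, EVI, NIRv, Red, LAI, Fpar, RHum, Rad, DEM, SoC`.
#' @param y yield in kg/ha, or `NA` for inference-only samples.
#' @return an object of class `season_tensor`.
#' @export
season_tensor <- function(county_id, year, x, y = NA_real_) {
  x <- as.matrix(x)
  if (ncol(x) != length(FEATURES))
    abort(sprintf("expected %d feature columns, got %d", length(FEATURES), ncol(x)),
          "wheatmoe_shape_error")
  if (is.null(colnames(x))) colnames(x) <- FEATURES
  if (!identical(colnames(x), FEATURES))
    abort("feature columns must be in canonical order", "wheatmoe_shape_error")
  rownames(x) <- MONTH_LABELS[seq_len(nrow(x))]
  structure(list(county_id = as.character(county_id), year = as.integer(year),
                 x = x, y = as.numeric(y)),
            class = "season_tensor")
}

#' @export
print.season_tensor <- function(x, ...) {
  cat(sprintf("<season_tensor> county %s, harvest year %d, %d months, yield %s kg/ha\n",
              x$county_id, x$year, nrow(x$x),
              if (is.na(x$y)) "NA" else format(x$y, digits = 6)))
  invisible(x)
}

#' Assemble a season tensor from monthly records
#'
#' Takes the monthly records of one county-year (long format, possibly with
#' missing months or missing feature values), orders them September to June,
#' fills interior gaps in the dynamic features by linear interpolation and
#' season ends by nearest-value extension, and broadcasts the static DEM/SoC
#' values across all 10 rows. A dynamic feature observed in fewer than
#' `min_months` months causes the record to be dropped with an
#' `insufficient-coverage` error carrying the reason.
#'
#' @param records data.frame with columns `month_index` (1..10) and the 10
#'   feature columns; missing months may simply be absent rows.
#' @param county_id,year sample identity.
#' @param y yield label (kg/ha) or `NA`.
#' @param min_months minimum observed months per dynamic feature (default 6).
#' @return a [season_tensor()].
#' @export
assemble_season <- function(records, county_id, year, y = NA_real_, min_months = 6L) {
  if (!"month_index" %in% names(records))
    abort("records must contain month_index", "wheatmoe_schema_error")
  m <- records$month_index
  if (any(m < 1 | m > SEASON_LENGTH)) abort("month_index outside 1..10", "wheatmoe_schema_error")
  if (anyDuplicated(m)) abort("duplicate month_index", "wheatmoe_schema_error")

  x <- matrix(NA_real_, SEASON_LENGTH, length(FEATURES), dimnames = list(MONTH_LABELS, FEATURES))
  for (f in FEATURES) {
    if (!f %in% names(records))
      abort(sprintf("missing feature column %s", f), "wheatmoe_schema_error")
    x[m, f] <- records[[f]]
  }

  dynamic <- setdiff(FEATURES, STATIC_FEATURES)
  for (f in dynamic) {
    obs <- which(!is.na(x[, f]))
    if (length(obs) < min_months)
      abort(sprintf("county %s year %d: feature %s observed in %d months (< %d)",
                    county_id, year, f, length(obs), min_months),
            "wheatmoe_insufficient_coverage")
    if (length(obs) < SEASON_LENGTH) {
      # interior gaps: linear interpolation; season ends: nearest observation
      x[, f] <- stats::approx(obs, x[obs, f], xout = seq_len(SEASON_LENGTH),
                              method = "linear", rule = 2)$y
    }
  }
  for (f in STATIC_FEATURES) {
    v <- x[!is.na(x[, f]), f]
    if (length(v) == 0)
      abort(sprintf("county %s year %d: static feature %s never observed", county_id, year, f),
            "wheatmoe_insufficient_coverage")
    x[, f] <- v[1]
  }
  season_tensor(county_id, year, x, y)
}

#' Truncate a season tensor to its first m months
#'
#' Used by progressive in-season evaluation: keep September..month `m` only.
#'
#' @param sample a [season_tensor()].
#' @param m number of leading months to keep, 1..10.
#' @return a shortened `season_tensor` with `m` rows.
#' @export
truncate_to_month <- function(sample, m) {
  if (length(m) != 1 || is.na(m) || m < 1 || m > SEASON_LENGTH)
    abort("m must be in 1..10", "wheatmoe_invalid_argument")
  season_tensor(sample$county_id, sample$year, sample$x[seq_len(m), , drop = FALSE], sample$y)
}

dataset_years <- function(samples) sort(unique(vapply(samples, `[[`, integer(1), "year")))
dataset_keys <- function(samples)
  vapply(samples, function(s) paste0(s$county_id, ":", s$year), character(1))
dataset_yields <- function(samples) vapply(samples, `[[`, numeric(1), "y")
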