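# County-year tables are long (tidy) CSV: one row per county x harvest-year x
# month, with all 10 features and the yield repeated on every row of the
# county-year. Values are written with fixed 6-decimal formatting so files are
# byte-identical across platforms.

TABLE_COLUMNS <- c("county_id", "year", "month_index", FEATURES, "yield_kg_ha")

#' Write season tensors to a long county-year CSV
#'
#' @param samples list of [season_tensor()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_county_table <- function(samples, path) {
  rows <- lapply(samples, function(s) {
    t <- nrow(s$x)
    data.frame(county_id = s$county_id, year = s$year, month_index = seq_len(t),
               as.data.frame(s$x, row.names = FALSE),
               yield_kg_ha = s$y, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  num <- setdiff(TABLE_COLUMNS, c("county_id", "year", "month_index"))
  for (j in num) df[[j]] <- formatC(df[[j]], format = "f", digits = 6)
  utils::write.csv(df[TABLE_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long county-year CSV into season tensors
#'
#' Schema-validated: all columns must be present, `month_index` must lie in
#' 1..10, the (county, year, month) key must be unique, and the yield must be
#' constant within a county-year. Violations report the offending rows.
#'
#' @param path CSV path.
#' @param min_months minimum observed months per dynamic feature before a
#'   county-year is dropped (see [assemble_season()]); dropped records are
#'   reported via `message()`.
#' @return list of [season_tensor()].
#' @export
read_county_table <- function(path, min_months = 6L) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "wheatmoe_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TABLE_COLUMNS, names(df))
  if (length(missing_cols))
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
          "wheatmoe_schema_error")
  bad <- which(df$month_index < 1 | df$month_index > SEASON_LENGTH)
  if (length(bad))
    abort(sprintf("month_index outside 1..10 at row(s) %s", paste(utils::head(bad, 5), collapse = ", ")),
          "wheatmoe_schema_error")
  key <- paste(df$county_id, df$year, df$month_index)
  if (anyDuplicated(key))
    abort(sprintf("duplicate (county, year, month) key: %s", key[anyDuplicated(key)]),
          "wheatmoe_schema_error")

  out <- list()
  for (grp in split(df, paste(df$county_id, df$year, sep = ":"))) {
    yy <- unique(grp$yield_kg_ha[!is.na(grp$yield_kg_ha)])
    if (length(yy) > 1)
      abort(sprintf("yield not constant within county-year %s:%d", grp$county_id[1], grp$year[1]),
            "wheatmoe_schema_error")
    s <- tryCatch(
      assemble_season(grp, grp$county_id[1], grp$year[1],
                      y = if (length(yy)) yy else NA_real_, min_months = min_months),
      wheatmoe_insufficient_coverage = function(e) {
        message("dropped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(s)) out[[length(out) + 1L]] <- s
  }
  # deterministic order: county then year
  ord <- order(vapply(out, `[[`, character(1), "county_id"),
               vapply(out, `[[`, integer(1), "year"))
  out[ord]
}

#' Write per-sample predictions as CSV
#'
#' @param path output path.
#' @param samples list of [season_tensor()] the predictions belong to.
#' @param predicted predicted yields, kg/ha.
#' @return the path, invisibly.
#' @export
write_predictions <- function(path, samples, predicted) {
  df <- data.frame(county_id = vapply(samples, `[[`, character(1), "county_id"),
                   year = vapply(samples, `[[`, integer(1), "year"),
                   actual_kg_ha = formatC(dataset_yields(samples), format = "f", digits = 4),
                   predicted_kg_ha = formatC(predicted, format = "f", digits = 4))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metric table as CSV
#'
#' @param path output path.
#' @param metrics a data.frame of metric rows (e.g. from [rolling_protocol()])
#'   or a single `metric_set`.
#' @return the path, invisibly.
#' @export
write_metrics <- function(path, metrics) {
  if (inherits(metrics, "metric_set")) metrics <- as.data.frame(unclass(metrics))
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
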