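# Accuracy metrics and diagnostic summaries. All metrics are computed on the
# original kg/ha scale after inverse target scaling.

#' Regression metric set: R-squared, RMSE, MAE
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`,
#' `RMSE = sqrt(mean((y - yhat)^2))`, `MAE = mean(|y - yhat|)`.
#'
#' @param actual,estimated equal-length numeric vectors, kg/ha.
#' @return `metric_set` list with `r2`, `rmse`, `mae`, `n`. With zero variance
#'   in the actuals R-squared is undefined: `r2` is `NA` with a classed
#'   warning (RMSE and MAE are still returned).
#' @export
metric_set <- function(actual, estimated) {
  if (length(actual) != length(estimated))
    abort("actual and estimated must have equal length", "wheatmoe_invalid_argument")
  n <- length(actual)
  if (n < 2) abort("need at least 2 samples", "wheatmoe_invalid_argument")
  ss_tot <- sum((actual - mean(actual))^2)
  r2 <- if (ss_tot <= 0) {
    warning(warningCondition("R-squared undefined: zero variance in actuals",
                             class = "wheatmoe_undefined_metric"))
    NA_real_
  } else {
    1 - sum((actual - estimated)^2) / ss_tot
  }
  err <- actual - estimated
  structure(list(r2 = r2,
                 rmse = sqrt(mean(err^2)),
                 mae = mean(abs(err)), n = n),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("R2 = %.4f, RMSE = %.2f kg/ha, MAE = %.2f kg/ha (n = %d)\n",
              x$r2, x$rmse, x$mae, x$n))
  invisible(x)
}

#' Per-sample min/max agreement statistic
#'
#' `100 * min(actual, estimated) / max(actual, estimated)`, in percent to one
#' decimal (half away from zero). Symmetric in its arguments and in (0, 100].
#'
#' @param actual,estimated positive yields, kg/ha (vectorized).
#' @return accuracy in percent, rounded to one decimal.
#' @export
sample_accuracy <- function(actual, estimated) {
  if (any(actual <= 0) || any(estimated <= 0))
    abort("sample_accuracy requires positive values", "wheatmoe_invalid_argument")
  round_half_away(100 * pmin(actual, estimated) / pmax(actual, estimated), 1)
}

#' Stratify errors by yield level
#'
#' Bins samples by quantile intervals of the actual yield (terciles by
#' default: low / medium / high) and summarizes raw errors
#' (`estimated - actual`; negative medians mean underestimation) and absolute
#' errors by quartiles within each bin.
#'
#' @param actual,estimated kg/ha vectors.
#' @param n_bins number of quantile bins.
#' @return `error_stratification`: list with `edges` (bin boundaries) and a
#'   data.frame `table` of per-bin error quartiles and counts.
#' @export
stratify_errors <- function(actual, estimated, n_bins = 3L) {
  if (length(actual) < n_bins) abort("need at least n_bins samples", "wheatmoe_invalid_argument")
  edges <- stats::quantile(actual, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(actual, breaks = edges, include.lowest = TRUE, labels = FALSE)
  raw <- estimated - actual
  rows <- lapply(seq_len(n_bins), function(bk) {
    i <- bin == bk
    q_raw <- stats::quantile(raw[i], c(0.25, 0.5, 0.75))
    q_abs <- stats::quantile(abs(raw[i]), c(0.25, 0.5, 0.75))
    data.frame(bin = bk, n = sum(i),
               raw_q1 = q_raw[1], raw_median = q_raw[2], raw_q3 = q_raw[3],
               abs_q1 = q_abs[1], abs_median = q_abs[2], abs_q3 = q_abs[3],
               row.names = NULL)
  })
  structure(list(edges = edges, table = do.call(rbind, rows)),
            class = "error_stratification")
}

#' Correlation screening of features against each other and yield
#'
#' Pearson correlations for all feature pairs (computed over all
#' county-months) and between season-mean features and yield; pairs whose
#' absolute correlation exceeds `threshold` are flagged as collinearity risks.
#' Constant columns yield undefined correlations and are flagged as such.
#'
#' @param samples list of [season_tensor()] with yield labels.
#' @param features feature subset (default all 10).
#' @param threshold absolute-correlation flag threshold.
#' @return list: `feature_cor` (matrix), `yield_cor` (named vector),
#'   `flags` (data.frame of flagged pairs), `undefined` (constant columns).
#' @export
correlation_screen <- function(samples, features = FEATURES, threshold = 0.9) {
  if (length(samples) < 3) abort("need at least 3 samples", "wheatmoe_invalid_argument")
  allx <- do.call(rbind, lapply(samples, function(s) s$x[, features, drop = FALSE]))
  const <- names(which(apply(allx, 2, function(v) stats::sd(v) == 0)))
  C <- suppressWarnings(stats::cor(allx))
  means <- do.call(rbind, lapply(samples, function(s) colMeans(s$x[, features, drop = FALSE])))
  y <- dataset_yields(samples)
  yc <- suppressWarnings(apply(means, 2, stats::cor, y = y))
  pairs <- which(upper.tri(C) & (!is.na(C) & abs(C) > threshold), arr.ind = TRUE)
  flags <- data.frame(feature_a = features[pairs[, 1]], feature_b = features[pairs[, 2]],
                      r = C[pairs])
  list(feature_cor = C, yield_cor = yc, flags = flags, undefined = const,
       threshold = threshold)
}
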