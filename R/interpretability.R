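# Shapley-style feature attribution by expected gradients: for each sample to
# be explained, attributions are path integrals of the model's input gradient
# along straight lines from background samples to the sample, averaged over
# the background distribution (midpoint rule over the path). For a linear
# model this reduces to beta * (x - background mean), and the attribution sum
# satisfies local accuracy, sum(phi) ~= f(x) - E[f(background)], up to
# path-discretization error.

# gradient of the scalar prediction wrt the input cells, [b, t, f]
input_gradient <- function(model, X) {
  if (inherits(model, "wheatmoe_model")) {
    fw <- model_forward(model, X, training = FALSE)
    zero_grads(model)
    g <- model_backward(model, fw$cache, rep(1, dim(X)[1]))
    zero_grads(model)
    g
  } else if (is.list(model) && is.function(model$grad)) {
    model$grad(X)
  } else {
    abort("model does not expose input gradients", "wheatmoe_invalid_argument")
  }
}

predict_scalar <- function(model, X) {
  if (inherits(model, "wheatmoe_model")) model_forward(model, X)$yhat
  else model$forward(X)
}

#' Feature attribution by expected gradients
#'
#' @param model a trained `wheatmoe_model` in evaluation mode (or any list
#'   with `forward(X)` and `grad(X)` functions over `[b, t, f]` arrays).
#' @param background list of scaled [season_tensor()] (or array) representing
#'   the data distribution; a fixed subsample of size `background_size` is
#'   used.
#' @param explain samples to explain (list or array).
#' @param n_backgrounds background draws per explained sample.
#' @param n_alphas path points per background draw (midpoint rule).
#' @param background_size cap on the retained background set.
#' @param seed seed for the background draws.
#' @return `attribution_report`: `per_sample` (signed per-feature attributions
#'   summed over months, samples x features), `per_cell` (list of `t x f`
#'   matrices), `mean_abs` (per-feature mean absolute attribution),
#'   `ranking` (features, most important first), `pred` and `base` (mean
#'   background prediction) per sample.
#' @export
attribute <- function(model, background, explain, n_backgrounds = 8L, n_alphas = 8L,
                      background_size = 100L, seed = 0L) {
  bg <- if (is.list(background)) stack_batch(background) else background
  ex <- if (is.list(explain)) stack_batch(explain) else explain
  if (is.matrix(ex)) ex <- array(ex, c(1, nrow(ex), ncol(ex)))
  if (dim(bg)[1] == 0) abort("background must be non-empty", "wheatmoe_invalid_argument")
  set.seed(seed)
  if (dim(bg)[1] > background_size)
    bg <- bg[sample.int(dim(bg)[1], background_size), , , drop = FALSE]

  nE <- dim(ex)[1]; t <- dim(ex)[2]; f <- dim(ex)[3]
  alphas <- (seq_len(n_alphas) - 0.5) / n_alphas
  per_cell <- vector("list", nE)
  per_sample <- matrix(0, nE, f, dimnames = list(NULL, FEATURES[seq_len(f)]))
  pred <- numeric(nE)
  base <- mean(predict_scalar(model, bg))

  for (i in seq_len(nE)) {
    x <- ex[i, , , drop = FALSE]
    bidx <- sample.int(dim(bg)[1], n_backgrounds, replace = n_backgrounds > dim(bg)[1])
    n_draws <- n_backgrounds * n_alphas
    Xt <- array(0, c(n_draws, t, f))
    D <- array(0, c(n_draws, t, f))  # x - b per draw
    k <- 0L
    for (bj in bidx) {
      diffm <- x[1, , ] - bg[bj, , ]
      for (a in alphas) {
        k <- k + 1L
        Xt[k, , ] <- bg[bj, , ] + a * diffm
        D[k, , ] <- diffm
      }
    }
    Gr <- input_gradient(model, Xt)
    phi <- apply(Gr * D, c(2, 3), mean)  # t x f
    dimnames(phi) <- list(MONTH_LABELS[seq_len(t)], FEATURES[seq_len(f)])
    per_cell[[i]] <- phi
    per_sample[i, ] <- colSums(phi)
    pred[i] <- predict_scalar(model, x)
  }
  mean_abs <- colMeans(abs(per_sample))
  structure(list(per_sample = per_sample, per_cell = per_cell,
                 mean_abs = mean_abs,
                 ranking = names(sort(mean_abs, decreasing = TRUE)),
                 pred = pred, base = base),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("<attribution_report> mean |attribution| by feature:\n")
  print(round(sort(x$mean_abs, decreasing = TRUE), 5))
  invisible(x)
}

#' Export attribution triplets for beeswarm-style plotting
#'
#' @param report an [attribute()] result.
#' @param explain the explained samples (for the feature values).
#' @param path optional CSV path.
#' @return data.frame of (feature, value, attribution) rows; the value is the
#'   sample's season-mean of the feature.
#' @export
attribution_long <- function(report, explain, path = NULL) {
  vals <- do.call(rbind, lapply(explain, function(s) colMeans(s$x)))
  n <- nrow(report$per_sample)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(sample = i, feature = colnames(report$per_sample),
               value = vals[i, colnames(report$per_sample)],
               attribution = report$per_sample[i, ], row.names = NULL)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}
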