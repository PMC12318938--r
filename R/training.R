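# Training recipe: Adam at a constant learning rate, Huber loss on min-max
# scaled targets, global gradient-norm clipping at 1.0, best-validation-loss
# checkpointing. The scaler is always fitted on the training portion only;
# every sample key touched during fitting is logged so leakage can be audited.

#' Training configuration
#'
#' The `"paper"` profile is the published recipe (lr 1e-4, batch 32,
#' 600 epochs); the `"desk"` profile keeps the recipe's batch size and
#' clipping but uses 100 epochs with lr 1e-3 so that CPU-scale runs converge
#' within a test budget.
#'
#' @param profile preset, `"paper"` or `"desk"`.
#' @param lr learning rate (> 0, Adam).
#' @param batch_size minibatch size.
#' @param epochs training epochs (>= 1).
#' @param grad_clip global gradient-norm ceiling.
#' @param huber_delta Huber transition point in scaled-target units.
#' @param val_fraction validation share of the non-test samples.
#' @param seed integer seed controlling shuffling and dropout.
#' @param patience early-stopping patience in epochs; `Inf` (default)
#'   disables early stopping and validation is monitoring-only.
#' @return a `train_config` list.
#' @export
train_config <- function(profile = c("paper", "desk"), lr = NULL, batch_size = 32L,
                         epochs = NULL, grad_clip = 1.0, huber_delta = 1.0,
                         val_fraction = 0.2, seed = 0L, patience = Inf) {
  profile <- match.arg(profile)
  if (is.null(lr)) lr <- if (profile == "paper") 1e-4 else 1e-3
  if (is.null(epochs)) epochs <- if (profile == "paper") 600L else 100L
  if (lr < 0 || batch_size < 1 || epochs < 1 || grad_clip <= 0 || huber_delta <= 0 ||
      val_fraction <= 0 || val_fraction >= 1)
    abort("invalid training configuration", "wheatmoe_invalid_config")
  structure(list(profile = profile, lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), grad_clip = grad_clip,
                 huber_delta = huber_delta, val_fraction = val_fraction,
                 seed = as.integer(seed), patience = patience),
            class = "train_config")
}

#' Huber loss
#'
#' `0.5 r^2` for `|r| <= delta`, `delta (|r| - 0.5 delta)` otherwise, averaged
#' over the batch; robust to outlying yields while quadratic near zero.
#'
#' @param y,yhat actual and estimated values (same units).
#' @param delta transition point (> 0).
#' @return mean loss (scalar).
#' @export
huber_loss <- function(y, yhat, delta = 1.0) {
  if (delta <= 0) abort("delta must be positive", "wheatmoe_invalid_argument")
  r <- abs(y - yhat)
  mean(ifelse(r <= delta, 0.5 * r^2, delta * (r - 0.5 * delta)))
}

huber_grad <- function(y, yhat, delta = 1.0) {
  # d(mean loss)/d(yhat)
  r <- yhat - y
  ifelse(abs(r) <= delta, r, delta * sign(r)) / length(y)
}

copy_params <- function(model) as.list(model$P)
restore_params <- function(model, snap) {
  for (n in names(snap)) model$P[[n]] <- snap[[n]]
  invisible(model)
}

# global-norm clipping; returns the post-clip norm
clip_grads <- function(model, clip) {
  ns <- ls(model$G)
  gn <- sqrt(sum(vapply(ns, function(n) sum(model$G[[n]]^2), numeric(1))))
  if (is.finite(gn) && gn > clip) {
    sc <- clip / gn
    for (n in ns) model$G[[n]] <- model$G[[n]] * sc
    return(clip)
  }
  gn
}

adam_init <- function(model) {
  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$m <- list(); st$v <- list()
  st
}

adam_step <- function(model, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (n in ls(model$P)) {
    g <- model$G[[n]]
    if (is.null(g)) next
    m <- st$m[[n]]; v <- st$v[[n]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    st$m[[n]] <- m; st$v[[n]] <- v
    model$P[[n]] <- model$P[[n]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  invisible(model)
}

#' Fixed-test-year split
#'
#' All samples from `test_years` form the test set; the remaining samples are
#' randomly partitioned into training and validation at `1 - val_fraction` :
#' `val_fraction` (seeded, sample-level).
#'
#' @param samples list of [season_tensor()].
#' @param test_years integer years held out for testing.
#' @param val_fraction validation share of the remaining samples.
#' @param seed split seed.
#' @return `split_spec`: list of index vectors `train`, `val`, `test`.
#' @export
fixed_year_split <- function(samples, test_years, val_fraction = 0.2, seed = 0L) {
  yrs <- vapply(samples, `[[`, integer(1), "year")
  absent <- setdiff(test_years, yrs)
  if (length(absent))
    abort(sprintf("test year(s) absent from data: %s", paste(absent, collapse = ", ")),
          "wheatmoe_invalid_argument")
  test <- which(yrs %in% test_years)
  rest <- which(!yrs %in% test_years)
  if (!length(rest)) abort("no samples left for training", "wheatmoe_invalid_argument")
  set.seed(seed)
  rest <- sample(rest)
  n_val <- round(length(rest) * val_fraction)
  structure(list(train = sort(rest[seq_len(length(rest) - n_val)]),
                 val = sort(rest[seq.int(length(rest) - n_val + 1, length(rest))]),
                 test = test, test_years = test_years, seed = seed,
                 mode = "fixed_years"),
            class = "split_spec")
}

#' Train a model
#'
#' Fits the min-max scaler on the training split only, then runs minibatch
#' Adam with Huber loss on scaled targets, clipping the global gradient norm
#' each step. The parameters with the best validation loss are restored at the
#' end. Deterministic given `cfg$seed`.
#'
#' @param model a freshly built `wheatmoe_model` (modified in place).
#' @param samples full list of [season_tensor()] the split indexes into.
#' @param split a `split_spec` from [fixed_year_split()] (or any list with
#'   `train` and `val` index vectors).
#' @param cfg a [train_config()].
#' @return list: `model`, `scaler`, `history` (per-epoch train/val loss),
#'   `grad_norms` (post-clip global norm per step), `best_epoch`, and
#'   `access_log` recording exactly which sample keys the scaler and the
#'   optimizer touched.
#' @export
train <- function(model, samples, split, cfg = train_config()) {
  if (!length(split$train) || !length(split$val))
    abort("empty training or validation split", "wheatmoe_invalid_argument")
  set.seed(cfg$seed)
  scaler <- fit_scaler(samples[split$train], scale_target = TRUE)
  tr <- apply_scaler(scaler, samples[split$train])
  va <- apply_scaler(scaler, samples[split$val])
  Xtr <- stack_batch(tr); ytr <- dataset_yields(tr)
  Xva <- stack_batch(va); yva <- dataset_yields(va)
  n <- length(ytr)

  st <- adam_init(model)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))
  grad_norms <- numeric(0)
  best_val <- Inf; best_epoch <- NA_integer_; best_snap <- NULL; stall <- 0L

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      fw <- model_forward(model, Xtr[idx, , , drop = FALSE], training = TRUE)
      loss <- huber_loss(ytr[idx], fw$yhat, cfg$huber_delta)
      ep_loss <- ep_loss + loss * length(idx)
      if (cfg$lr > 0) {
        zero_grads(model)
        model_backward(model, fw$cache, huber_grad(ytr[idx], fw$yhat, cfg$huber_delta))
        grad_norms <- c(grad_norms, clip_grads(model, cfg$grad_clip))
        adam_step(model, st, cfg$lr)
      }
    }
    val_loss <- huber_loss(yva, model_forward(model, Xva)$yhat, cfg$huber_delta)
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / n,
                                         val_loss = val_loss))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_epoch <- ep; best_snap <- copy_params(model); stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  if (!is.null(best_snap)) restore_params(model, best_snap)
  list(model = model, scaler = scaler, history = history, grad_norms = grad_norms,
       best_epoch = best_epoch,
       access_log = list(scaler_keys = scaler$seen_keys,
                         train_keys = dataset_keys(samples[split$train]),
                         val_keys = dataset_keys(samples[split$val])))
}

evaluate_fit <- function(fit, samples, idx) {
  te <- apply_scaler(fit$scaler, samples[idx])
  yhat <- inverse_target(fit$scaler, model_forward(fit$model, stack_batch(te))$yhat)
  metric_set(dataset_yields(samples[idx]), yhat)
}

#' Leave-one-year-out rolling evaluation
#'
#' Each year in turn is the test set; the remaining years are split 80/20 into
#' training and validation at the sample level, a fresh model is trained, and
#' test metrics are computed in kg/ha. A mean row is appended.
#'
#' @param samples list of [season_tensor()] spanning at least 3 years.
#' @param model_factory `function(seed)` returning a fresh `wheatmoe_model`.
#' @param cfg a [train_config()].
#' @param years years to roll over (default: all years present).
#' @return data.frame with one row per test year (`year`, `r2`, `rmse`,
#'   `mae`, `n`) plus a final `mean` row.
#' @export
rolling_protocol <- function(samples, model_factory, cfg = train_config(), years = NULL) {
  yrs <- years %||% dataset_years(samples)
  if (length(yrs) < 3) abort("rolling protocol needs >= 3 distinct years", "wheatmoe_invalid_argument")
  rows <- vector("list", length(yrs))
  for (i in seq_along(yrs)) {
    seed_i <- cfg$seed + 7919L * i
    split <- fixed_year_split(samples, yrs[i], cfg$val_fraction, seed = seed_i)
    set.seed(seed_i)
    model <- model_factory(seed_i)
    cfg_i <- cfg; cfg_i$seed <- seed_i
    fit <- train(model, samples, split, cfg_i)
    m <- evaluate_fit(fit, samples, split$test)
    rows[[i]] <- data.frame(year = yrs[i], r2 = m$r2, rmse = m$rmse, mae = m$mae, n = m$n)
  }
  out <- do.call(rbind, rows)
  rbind(out, data.frame(year = NA_integer_, r2 = mean(out$r2), rmse = mean(out$rmse),
                        mae = mean(out$mae), n = sum(out$n)))
}

#' Progressive in-season (monthly truncation) evaluation
#'
#' For each cutoff month `m`, all sequences are truncated to their first `m`
#' months, a fresh model is trained on the truncated training split, and test
#' metrics are computed; the resulting monthly R-squared/RMSE curve quantifies
#' how early in the season yield becomes predictable.
#'
#' @param samples list of [season_tensor()].
#' @param months cutoff months to evaluate (subset of 1..10).
#' @param model_factory `function(seed)` returning a fresh model.
#' @param cfg a [train_config()].
#' @param split a `split_spec`; by default the last year is held out.
#' @return data.frame with one row per cutoff (`month`, `r2`, `rmse`, `mae`).
#' @export
progressive_monthly_eval <- function(samples, months = 1:10, model_factory,
                                     cfg = train_config(), split = NULL) {
  if (is.null(split)) {
    yrs <- dataset_years(samples)
    split <- fixed_year_split(samples, yrs[length(yrs)], cfg$val_fraction, seed = cfg$seed)
  }
  rows <- vector("list", length(months))
  for (j in seq_along(months)) {
    m <- months[j]
    trunc <- lapply(samples, truncate_to_month, m = m)
    seed_j <- cfg$seed + 104729L * j
    set.seed(seed_j)
    model <- model_factory(seed_j)
    cfg_j <- cfg; cfg_j$seed <- seed_j
    fit <- train(model, trunc, split, cfg_j)
    met <- evaluate_fit(fit, trunc, split$test)
    rows[[j]] <- data.frame(month = m, r2 = met$r2, rmse = met$rmse, mae = met$mae)
  }
  do.call(rbind, rows)
}

#' Ablation study over model variants
#'
#' Trains each requested variant on the same split and reports test metrics
#' together with the analytic per-sample FLOP count.
#'
#' @param samples list of [season_tensor()].
#' @param split a `split_spec`.
#' @param variants variant names (default: the four ablation rows).
#' @param config a [model_config()].
#' @param cfg a [train_config()].
#' @return data.frame: `variant`, `r2`, `rmse`, `mae`, `flops`.
#' @export
ablate <- function(samples, split,
                   variants = c("stf_moe", "stf_no_moe", "stf_single_expert", "stf_moe_dense"),
                   config = model_config("desk"), cfg = train_config("desk")) {
  rows <- lapply(seq_along(variants), function(i) {
    v <- variants[i]
    seed_i <- cfg$seed + 31L * i
    set.seed(seed_i)
    model <- build_variant(v, config, seed = seed_i)
    cfg_i <- cfg; cfg_i$seed <- seed_i
    fit <- train(model, samples, split, cfg_i)
    met <- evaluate_fit(fit, samples, split$test)
    data.frame(variant = v, r2 = met$r2, rmse = met$rmse, mae = met$mae,
               flops = count_flops(model))
  })
  do.call(rbind, rows)
}
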