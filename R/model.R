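# The yield estimator: a linear embedding with sinusoidal positional encoding
# feeds two parallel branches -- a Transformer encoder (global season context)
# and a bidirectional LSTM (local temporal dynamics). Their concatenation is
# routed by a softmax gating network to a pool of five architecturally
# heterogeneous experts with sparse Top-2 activation; per-expert linear
# adapters standardize output widths before the gate-weighted sum. A fusion
# head combines the expert mixture with both branches' final states into a
# scalar (scaled) yield.

MODEL_VARIANTS <- c("lstm", "transformer", "lstm_transformer", "stf_moe",
                    "stf_no_moe", "stf_single_expert", "stf_moe_dense")

#' Model configuration
#'
#' The architecture shape follows the published recipe: 4 encoder layers with
#' 8 attention heads, a 2-layer bidirectional LSTM, 5 experts with Top-2
#' sparse gating, a 256-unit gate hidden layer and a 512 -> 256 fusion head.
#' The hidden width `d` is not fixed by the recipe; the `"paper"` profile uses
#' d = 128, the `"desk"` profile a CPU-friendly d = 32 with proportionally
#' smaller gate/fusion widths for test-scale training runs.
#'
#' @param profile `"paper"` or `"desk"` preset.
#' @param d hidden width; must be divisible by `n_heads` and by 4.
#' @param n_enc_layers,n_heads Transformer encoder depth and heads per layer.
#' @param lstm_layers bidirectional LSTM depth (per-direction width d/2).
#' @param n_experts,top_k expert pool size and sparse activation count.
#' @param gate_hidden gating network hidden width.
#' @param fusion_dims two widths of the fusion head.
#' @param ff_dim encoder feed-forward inner width.
#' @param dropout named list: `emb`, `enc`, `lstm`, `fusion` rates (the
#'   experts' dropout rates are part of their architectural definitions).
#' @param input_features,max_seq_len input schema (10 features, 10 months).
#' @param renormalize_topk renormalize the Top-k gate weights to sum to one?
#'   Off by default: the mixture uses the raw softmax entries.
#' @return a `model_config` list.
#' @export
model_config <- function(profile = c("paper", "desk"), d = NULL,
                         n_enc_layers = 4L, n_heads = 8L, lstm_layers = 2L,
                         n_experts = 5L, top_k = 2L, gate_hidden = NULL,
                         fusion_dims = NULL, ff_dim = NULL,
                         dropout = list(emb = 0.1, enc = 0.1, lstm = 0.2, fusion = 0.1),
                         input_features = 10L, max_seq_len = 10L,
                         renormalize_topk = FALSE) {
  profile <- match.arg(profile)
  if (is.null(d)) d <- if (profile == "paper") 128L else 32L
  if (is.null(gate_hidden)) gate_hidden <- if (profile == "paper") 256L else 2L * d
  if (is.null(fusion_dims)) fusion_dims <- if (profile == "paper") c(512L, 256L) else c(128L, 64L)
  if (is.null(ff_dim)) ff_dim <- 4L * d
  if (d %% n_heads != 0) abort("d must be divisible by n_heads", "wheatmoe_config_error")
  if (d %% 4 != 0) abort("d must be divisible by 4", "wheatmoe_config_error")
  if (top_k > n_experts) abort("top_k must be <= n_experts", "wheatmoe_config_error")
  if (n_experts != 5L) abort("the expert pool is defined for exactly 5 experts", "wheatmoe_config_error")
  structure(list(profile = profile, d = as.integer(d), n_enc_layers = as.integer(n_enc_layers),
                 n_heads = as.integer(n_heads), lstm_layers = as.integer(lstm_layers),
                 n_experts = as.integer(n_experts), top_k = as.integer(top_k),
                 gate_hidden = as.integer(gate_hidden), fusion_dims = as.integer(fusion_dims),
                 ff_dim = as.integer(ff_dim), dropout = dropout,
                 input_features = as.integer(input_features),
                 max_seq_len = as.integer(max_seq_len),
                 renormalize_topk = isTRUE(renormalize_topk)),
            class = "model_config")
}

# Resolved architecture of the five heterogeneous experts. Widths are relative
# to the hidden width d; input is the temporally averaged 2d-vector. `drop`
# rates apply after the activation of each layer ("none" = linear layer).
expert_spec <- function(expert_id, d) {
  switch(as.character(expert_id),
    "0" = list(widths = c(d, d), acts = c("gelu", "gelu"), drop = c(0.2, 0.1)),
    "1" = list(widths = c(2 * d, d), acts = c("relu", "none"), drop = c(0.3, 0)),
    "2" = list(widths = c(d / 2, d / 2), acts = c("silu", "silu"), drop = c(0.1, 0)),
    "3" = list(widths = c(d), acts = c("gelu"), drop = c(0)),
    "4" = list(widths = c(d / 2, d / 2, d), acts = c("relu", "relu", "none"), drop = c(0.2, 0.2, 0)),
    abort(sprintf("unknown expert_id %s", expert_id), "wheatmoe_config_error"))
}

acc_grad <- function(G, name, g) {
  cur <- G[[name]]
  G[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

zero_grads <- function(model) {
  rm(list = ls(model$G), envir = model$G)
  invisible(model)
}

reset_counter <- function(model) {
  model$counter$calls <- 0L
  model$counter$per_expert <- numeric(model$config$n_experts)
  invisible(model)
}

variant_branches <- function(variant) {
  list(has_T = variant != "lstm",
       has_L = variant != "transformer",
       moe = switch(variant, stf_moe = "sparse", stf_moe_dense = "dense",
                    stf_single_expert = "single", "none"))
}

#' Build a model variant
#'
#' `stf_moe` is the full model; `stf_no_moe` drops the expert block and fuses
#' the two branch final states only; `stf_single_expert` routes everything
#' through expert 0 with weight one; `stf_moe_dense` evaluates all five
#' experts weighted by the full softmax (no Top-2). `lstm`, `transformer` and
#' `lstm_transformer` are the baselines sharing the embedding and head
#' conventions (`lstm_transformer` has the same computation graph as
#' `stf_no_moe`).
#'
#' @param name one of
#'   `lstm, transformer, lstm_transformer, stf_moe, stf_no_moe, stf_single_expert, stf_moe_dense`.
#' @param config a [model_config()].
#' @param seed optional integer seed for parameter initialization.
#' @return a `wheatmoe_model` environment holding parameters `P`, gradient
#'   accumulators `G`, and an expert-call counter.
#' @export
build_variant <- function(name, config = model_config(), seed = NULL) {
  if (!name %in% MODEL_VARIANTS)
    abort(sprintf("unknown variant '%s'", name), "wheatmoe_config_error")
  if (!is.null(seed)) set.seed(seed)
  d <- config$d
  br <- variant_branches(name)
  model <- new.env(parent = emptyenv())
  model$variant <- name
  model$config <- config
  model$P <- new.env(parent = emptyenv())
  model$G <- new.env(parent = emptyenv())
  model$counter <- new.env(parent = emptyenv())
  P <- model$P

  P[["emb.W"]] <- glorot(config$input_features, d)
  P[["emb.b"]] <- numeric(d)

  if (br$has_T) {
    for (l in seq_len(config$n_enc_layers)) {
      pre <- sprintf("enc%d", l)
      for (w in c("Wq", "Wk", "Wv", "Wo")) P[[paste0(pre, ".", w)]] <- glorot(d, d)
      for (b in c("bq", "bk", "bv", "bo")) P[[paste0(pre, ".", b)]] <- numeric(d)
      P[[paste0(pre, ".ln1.g")]] <- rep(1, d); P[[paste0(pre, ".ln1.b")]] <- numeric(d)
      P[[paste0(pre, ".ln2.g")]] <- rep(1, d); P[[paste0(pre, ".ln2.b")]] <- numeric(d)
      P[[paste0(pre, ".ff.W1")]] <- glorot(d, config$ff_dim)
      P[[paste0(pre, ".ff.b1")]] <- numeric(config$ff_dim)
      P[[paste0(pre, ".ff.W2")]] <- glorot(config$ff_dim, d)
      P[[paste0(pre, ".ff.b2")]] <- numeric(d)
    }
  }
  if (br$has_L) {
    Hd <- d %/% 2L
    for (l in seq_len(config$lstm_layers)) {
      d_in <- d  # layer 1 sees the embedding; deeper layers the 2*Hd = d concat
      for (dir in c("f", "r")) {
        P[[sprintf("lstm%d.%s.W", l, dir)]] <- glorot(d_in, 4 * Hd)
        P[[sprintf("lstm%d.%s.U", l, dir)]] <- glorot(Hd, 4 * Hd)
        b0 <- numeric(4 * Hd)
        b0[(Hd + 1):(2 * Hd)] <- 1  # forget-gate bias
        P[[sprintf("lstm%d.%s.b", l, dir)]] <- b0
      }
    }
  }
  if (br$moe %in% c("sparse", "dense")) {
    P[["gate.W1"]] <- glorot(2 * d, config$gate_hidden)
    P[["gate.b1"]] <- numeric(config$gate_hidden)
    P[["gate.W2"]] <- glorot(config$gate_hidden, config$n_experts)
    P[["gate.b2"]] <- numeric(config$n_experts)
  }
  if (br$moe != "none") {
    experts <- if (br$moe == "single") 0L else 0:(config$n_experts - 1L)
    for (e in experts) {
      sp <- expert_spec(e, d)
      d_in <- 2 * d
      for (l in seq_along(sp$widths)) {
        P[[sprintf("exp%d.W%d", e, l)]] <- glorot(d_in, sp$widths[l])
        P[[sprintf("exp%d.b%d", e, l)]] <- numeric(sp$widths[l])
        d_in <- sp$widths[l]
      }
      P[[sprintf("exp%d.Wa", e)]] <- glorot(d_in, d)
      P[[sprintf("exp%d.ba", e)]] <- numeric(d)
    }
  }
  fus_in <- d * ((br$moe != "none") + br$has_T + br$has_L)
  P[["fus.W1"]] <- glorot(fus_in, config$fusion_dims[1])
  P[["fus.b1"]] <- numeric(config$fusion_dims[1])
  P[["fus.W2"]] <- glorot(config$fusion_dims[1], config$fusion_dims[2])
  P[["fus.b2"]] <- numeric(config$fusion_dims[2])
  P[["fus.W3"]] <- glorot(config$fusion_dims[2], 1)
  P[["fus.b3"]] <- numeric(1)

  reset_counter(model)
  class(model) <- "wheatmoe_model"
  model
}

#' @export
print.wheatmoe_model <- function(x, ...) {
  np <- sum(vapply(ls(x$P), function(n) length(x$P[[n]]), numeric(1)))
  cat(sprintf("<wheatmoe_model> variant %s, d = %d, %s parameters\n",
              x$variant, x$config$d, format(np, big.mark = ",")))
  invisible(x)
}

# -- batching helpers --------------------------------------------------------

#' Stack season tensors into a batch array
#'
#' @param samples list of [season_tensor()] with equal month counts.
#' @return numeric array `[b, t, f]`.
#' @export
stack_batch <- function(samples) {
  t <- nrow(samples[[1]]$x)
  X <- array(0, c(length(samples), t, length(FEATURES)))
  for (i in seq_along(samples)) X[i, , ] <- samples[[i]]$x
  X
}

flatten_batch <- function(X) {
  # [b, t, f] -> (b*t) x f with time contiguous within sample
  A <- aperm(X, c(2, 1, 3))
  dim(A) <- c(dim(X)[1] * dim(X)[2], dim(X)[3])
  A
}

unflatten_batch <- function(M, b, t) {
  dim(M) <- c(t, b, ncol(M))
  aperm(M, c(2, 1, 3))
}

# -- gating ------------------------------------------------------------------

# batched gate on h_avg (b x 2d); returns probabilities, Top-k selection and
# caches for backprop
gate_batch <- function(h_avg, P, k, renormalize = FALSE) {
  l1 <- linear_fwd(h_avg, P[["gate.W1"]], P[["gate.b1"]])
  a1 <- gelu_fwd(l1$Y)
  l2 <- linear_fwd(a1$Y, P[["gate.W2"]], P[["gate.b2"]])
  g <- softmax_rows(l2$Y)
  n <- nrow(g)
  eps <- matrix(0L, n, k)
  w <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(-g[i, ], seq_len(ncol(g)))[seq_len(k)]  # ties -> lowest index
    eps[i, ] <- ord
    w[i, ] <- g[i, ord]
  }
  if (renormalize) w <- w / rowSums(w)
  list(g = g, eps = eps, w = w, l1 = l1, a1 = a1, l2 = l2, renormalize = renormalize)
}

#' Gate decision for one sample
#'
#' Averages the `t x 2d` fused branch representation over time, runs the
#' two-layer gating network (`softmax(W2 GELU(W1 h_avg + b1) + b2)`), and
#' selects the Top-k experts. Ties are broken deterministically by lowest
#' expert index; the returned weights are the raw softmax entries (not
#' renormalized) unless `renormalize` is set.
#'
#' @param h `t x 2d` matrix (one sample's concatenated branch outputs) or an
#'   already-averaged numeric vector of length 2d.
#' @param params list with `W1` (2d x gate_hidden), `b1`, `W2`
#'   (gate_hidden x n_experts), `b2`.
#' @param top_k number of experts to select.
#' @param renormalize renormalize the selected weights to sum to 1?
#' @return list with `g` (probability vector), `epsilon` (0-based expert
#'   indices), `w` (their weights), `k`.
#' @export
gate_decision <- function(h, params, top_k = 2L, renormalize = FALSE) {
  if (is.matrix(h)) {
    stopifnot_finite(h, "gate input h")
    h_avg <- colMeans(h)
  } else {
    stopifnot_finite(h, "gate input h")
    h_avg <- h
  }
  P <- list("gate.W1" = params$W1, "gate.b1" = params$b1,
            "gate.W2" = params$W2, "gate.b2" = params$b2)
  gb <- gate_batch(matrix(h_avg, 1), P, top_k, renormalize)
  list(g = drop(gb$g), epsilon = as.integer(gb$eps[1, ] - 1L),
       w = drop(gb$w), k = as.integer(top_k))
}

# -- experts -----------------------------------------------------------------

# batched expert MLP; X: n x 2d rows of h_avg
expert_fwd <- function(X, e, P, training) {
  sp <- expert_spec(e, ncol(X) / 2)
  caches <- vector("list", length(sp$widths))
  H <- X
  for (l in seq_along(sp$widths)) {
    lin <- linear_fwd(H, P[[sprintf("exp%d.W%d", e, l)]], P[[sprintf("exp%d.b%d", e, l)]])
    if (sp$acts[l] == "none") {
      A <- lin$Y; dr <- list(Y = A, mask = NULL)
    } else {
      A <- act_fun(sp$acts[l])$f(lin$Y)
      dr <- dropout_fwd(A, sp$drop[l], training)
    }
    caches[[l]] <- list(lin = lin, act = sp$acts[l])
    H <- dr$Y
    caches[[l]]$dr <- dr
  }
  list(Y = H, caches = caches, spec = sp)
}

expert_bwd <- function(dY, fwd, e, P, G) {
  sp <- fwd$spec
  dH <- dY
  for (l in rev(seq_along(sp$widths))) {
    cc <- fwd$caches[[l]]
    dH <- dropout_bwd(dH, cc$dr)
    if (cc$act != "none") dH <- dH * act_fun(cc$act)$df(cc$lin$Y)
    gl <- linear_bwd(dH, cc$lin, P[[sprintf("exp%d.W%d", e, l)]])
    acc_grad(G, sprintf("exp%d.W%d", e, l), gl$dW)
    acc_grad(G, sprintf("exp%d.b%d", e, l), gl$db)
    dH <- gl$dX
  }
  dH
}

#' Evaluate one expert network
#'
#' Runs expert `expert_id` (0..4) of a built model on a 2d input vector (or
#' `n x 2d` matrix) without the adapter. Deterministic in evaluation mode
#' (dropout disabled).
#'
#' @param model a `wheatmoe_model` containing the expert's parameters.
#' @param expert_id integer 0..4.
#' @param x numeric vector of length 2d or matrix `n x 2d`.
#' @param training apply the expert's dropout layers?
#' @return the expert's native output (vector or matrix).
#' @export
expert_forward <- function(model, expert_id, x, training = FALSE) {
  if (is.null(model$P[[sprintf("exp%d.W1", expert_id)]]))
    abort(sprintf("model has no expert %d", expert_id), "wheatmoe_config_error")
  single <- !is.matrix(x)
  if (single) x <- matrix(x, 1)
  out <- expert_fwd(x, expert_id, model$P, training)$Y
  if (single) drop(out) else out
}

# evaluates the mixture for selected experts; rows_by_expert: list keyed by
# expert id (character) of row indices; wmat: n x n_experts weights (0 where
# not selected)
moe_mixture_fwd <- function(h_avg, wmat, model, training) {
  d <- model$config$d
  n <- nrow(h_avg)
  O <- matrix(0, n, d)
  per_expert <- vector("list", model$config$n_experts)
  for (e in 0:(model$config$n_experts - 1L)) {
    rows <- which(wmat[, e + 1L] != 0)
    if (!length(rows)) next
    fwd <- expert_fwd(h_avg[rows, , drop = FALSE], e, model$P, training)
    ad <- linear_fwd(fwd$Y, model$P[[sprintf("exp%d.Wa", e)]], model$P[[sprintf("exp%d.ba", e)]])
    O[rows, ] <- O[rows, ] + wmat[rows, e + 1L] * ad$Y
    per_expert[[e + 1L]] <- list(rows = rows, fwd = fwd, ad = ad)
    model$counter$calls <- model$counter$calls + length(rows)
    model$counter$per_expert[e + 1L] <- model$counter$per_expert[e + 1L] + length(rows)
  }
  list(Y = O, per_expert = per_expert, wmat = wmat)
}

# returns dh_avg and dW (n x n_experts gradient wrt the mixture weights)
moe_mixture_bwd <- function(dO, cache, model) {
  G <- model$G; P <- model$P
  n <- nrow(dO)
  dh_avg <- matrix(0, n, 2 * model$config$d)
  dwmat <- matrix(0, n, model$config$n_experts)
  for (e in 0:(model$config$n_experts - 1L)) {
    pe <- cache$per_expert[[e + 1L]]
    if (is.null(pe)) next
    rows <- pe$rows
    w <- cache$wmat[rows, e + 1L]
    dOc <- dO[rows, , drop = FALSE]
    dwmat[rows, e + 1L] <- rowSums(dOc * pe$ad$Y)
    dAd <- dOc * w
    gl <- linear_bwd(dAd, pe$ad, P[[sprintf("exp%d.Wa", e)]])
    acc_grad(G, sprintf("exp%d.Wa", e), gl$dW)
    acc_grad(G, sprintf("exp%d.ba", e), gl$db)
    dh_avg[rows, ] <- dh_avg[rows, ] + expert_bwd(gl$dX, pe$fwd, e, P, G)
  }
  list(dh_avg = dh_avg, dwmat = dwmat)
}

#' Sparse mixture-of-experts forward pass for one sample
#'
#' Gates the sample, evaluates exactly the Top-k selected experts (observable
#' via the model's call counter), adapts their outputs to width d, and returns
#' the gate-weighted sum.
#'
#' @param model a `wheatmoe_model` with gate and experts (variant `stf_moe` or
#'   `stf_moe_dense`).
#' @param h `t x 2d` matrix of concatenated branch outputs for one sample.
#' @param training training mode (dropout active)?
#' @return list with `o_moe` (length-d vector) and the gate `decision`.
#' @export
moe_forward <- function(model, h, training = FALSE) {
  stopifnot_finite(h, "h")
  cfg <- model$config
  h_avg <- matrix(colMeans(h), 1)
  dec <- gate_decision(h, list(W1 = model$P[["gate.W1"]], b1 = model$P[["gate.b1"]],
                               W2 = model$P[["gate.W2"]], b2 = model$P[["gate.b2"]]),
                       top_k = cfg$top_k, renormalize = cfg$renormalize_topk)
  wmat <- matrix(0, 1, cfg$n_experts)
  if (model$variant == "stf_moe_dense") {
    wmat[1, ] <- dec$g
  } else {
    wmat[1, dec$epsilon + 1L] <- dec$w
  }
  mix <- moe_mixture_fwd(h_avg, wmat, model, training)
  list(o_moe = drop(mix$Y), decision = dec)
}

# -- full forward / backward -------------------------------------------------

model_forward <- function(model, X, training = FALSE, collect = FALSE) {
  cfg <- model$config
  if (is.matrix(X)) X <- array(X, c(1, nrow(X), ncol(X)))
  b <- dim(X)[1]; t <- dim(X)[2]
  if (dim(X)[3] != cfg$input_features)
    abort(sprintf("expected %d input features, got %d", cfg$input_features, dim(X)[3]),
          "wheatmoe_shape_error")
  if (t > cfg$max_seq_len) abort("sequence longer than max_seq_len", "wheatmoe_shape_error")
  br <- variant_branches(model$variant)
  P <- model$P
  cache <- list(b = b, t = t, br = br)

  Xf <- flatten_batch(X)
  emb <- linear_fwd(Xf, P[["emb.W"]], P[["emb.b"]])
  H <- emb$Y
  if (br$has_T) {
    PE <- positional_encoding(t, cfg$d)
    H <- H + PE[rep(seq_len(t), b), , drop = FALSE]
  }
  dre <- dropout_fwd(H, cfg$dropout$emb, training)
  H0 <- dre$Y
  cache$emb <- emb; cache$dre <- dre

  idx_last <- seq_len(b) * t
  parts <- list(); dparts <- character(0)

  if (br$has_T) {
    enc <- vector("list", cfg$n_enc_layers)
    Ht <- H0
    for (l in seq_len(cfg$n_enc_layers)) {
      enc[[l]] <- encoder_layer_fwd(Ht, P, sprintf("enc%d", l), cfg$n_heads, b, t,
                                    cfg$dropout$enc, training)
      Ht <- enc[[l]]$Y
    }
    cache$enc <- enc
    cache$h_T <- Ht
    final_T <- Ht[idx_last, , drop = FALSE]
  }
  if (br$has_L) {
    lst <- bilstm_fwd(H0, P, cfg$lstm_layers, b, t, cfg$dropout$lstm, training)
    cache$lstm <- lst
    final_L <- lst$final
  }

  if (br$moe != "none") {
    hcat <- cbind(cache$h_T, cache$lstm$Y)
    if (any(!is.finite(hcat)))
      abort("non-finite values reached the gate", "wheatmoe_nonfinite")
    grp <- rep(seq_len(b), each = t)
    h_avg <- rowsum(hcat, grp) / t
    cache$h_avg <- h_avg
    wmat <- matrix(0, b, cfg$n_experts)
    if (br$moe == "single") {
      wmat[, 1] <- 1
      gb <- NULL
    } else {
      gb <- gate_batch(h_avg, P, cfg$top_k, cfg$renormalize_topk)
      if (br$moe == "dense") {
        wmat <- gb$g
      } else {
        for (i in seq_len(b)) wmat[i, gb$eps[i, ]] <- gb$w[i, ]
      }
    }
    cache$gb <- gb
    mix <- moe_mixture_fwd(h_avg, wmat, model, training)
    cache$mix <- mix
    parts$o_moe <- mix$Y
  }
  if (br$has_T) parts$final_T <- final_T
  if (br$has_L) parts$final_L <- final_L
  Z <- do.call(cbind, parts)
  cache$part_names <- names(parts)

  f1 <- linear_fwd(Z, P[["fus.W1"]], P[["fus.b1"]])
  a1 <- gelu_fwd(f1$Y)
  d1 <- dropout_fwd(a1$Y, cfg$dropout$fusion, training)
  f2 <- linear_fwd(d1$Y, P[["fus.W2"]], P[["fus.b2"]])
  a2 <- gelu_fwd(f2$Y)
  d2 <- dropout_fwd(a2$Y, cfg$dropout$fusion, training)
  f3 <- linear_fwd(d2$Y, P[["fus.W3"]], P[["fus.b3"]])
  cache$fus <- list(f1 = f1, a1 = a1, d1 = d1, f2 = f2, a2 = a2, d2 = d2, f3 = f3)

  out <- list(yhat = drop(f3$Y), cache = cache)
  if (collect) {
    out$h_avg <- cache$h_avg
    out$g <- cache$gb$g
    out$eps <- cache$gb$eps
    out$w <- cache$gb$w
    out$o_moe <- parts$o_moe
    out$final_T <- parts$final_T
    out$final_L <- parts$final_L
  }
  out
}

model_backward <- function(model, cache, dy) {
  cfg <- model$config; P <- model$P; G <- model$G
  b <- cache$b; t <- cache$t; br <- cache$br
  fus <- cache$fus
  dY <- matrix(dy, ncol = 1)
  g3 <- linear_bwd(dY, fus$f3, P[["fus.W3"]])
  acc_grad(G, "fus.W3", g3$dW); acc_grad(G, "fus.b3", g3$db)
  dA2 <- gelu_bwd(dropout_bwd(g3$dX, fus$d2), fus$a2)
  g2 <- linear_bwd(dA2, fus$f2, P[["fus.W2"]])
  acc_grad(G, "fus.W2", g2$dW); acc_grad(G, "fus.b2", g2$db)
  dA1 <- gelu_bwd(dropout_bwd(g2$dX, fus$d1), fus$a1)
  g1 <- linear_bwd(dA1, fus$f1, P[["fus.W1"]])
  acc_grad(G, "fus.W1", g1$dW); acc_grad(G, "fus.b1", g1$db)
  dZ <- g1$dX

  # split fusion input gradient back into its parts
  d <- cfg$d
  off <- 0L
  dpart <- list()
  for (nm in cache$part_names) {
    dpart[[nm]] <- dZ[, (off + 1):(off + d), drop = FALSE]
    off <- off + d
  }

  dh_T <- NULL; dh_L <- NULL; dfinal_L <- NULL
  if (br$has_T) dh_T <- matrix(0, b * t, d)
  if (br$has_L) dh_L <- matrix(0, b * t, d)

  if (br$moe != "none") {
    mb <- moe_mixture_bwd(dpart$o_moe, cache$mix, model)
    dh_avg <- mb$dh_avg
    if (!is.null(cache$gb)) {
      gb <- cache$gb
      q <- matrix(0, b, cfg$n_experts)
      if (br$moe == "dense") {
        q <- mb$dwmat
      } else if (gb$renormalize) {
        for (i in seq_len(b)) {
          sel <- gb$eps[i, ]
          qs <- mb$dwmat[i, sel]
          S <- sum(gb$g[i, sel])
          wn <- gb$w[i, ]
          q[i, sel] <- (qs - sum(wn * qs)) / S
        }
      } else {
        for (i in seq_len(b)) q[i, gb$eps[i, ]] <- mb$dwmat[i, gb$eps[i, ]]
      }
      dlogits <- softmax_rows_bwd(q, gb$g)
      gl2 <- linear_bwd(dlogits, gb$l2, P[["gate.W2"]])
      acc_grad(G, "gate.W2", gl2$dW); acc_grad(G, "gate.b2", gl2$db)
      da1 <- gelu_bwd(gl2$dX, gb$a1)
      gl1 <- linear_bwd(da1, gb$l1, P[["gate.W1"]])
      acc_grad(G, "gate.W1", gl1$dW); acc_grad(G, "gate.b1", gl1$db)
      dh_avg <- dh_avg + gl1$dX
    }
    # distribute the temporal-mean gradient back to every time step
    dh_rows <- dh_avg[rep(seq_len(b), each = t), , drop = FALSE] / t
    dh_T <- dh_T + dh_rows[, 1:d, drop = FALSE]
    dh_L <- dh_L + dh_rows[, (d + 1):(2 * d), drop = FALSE]
  }

  idx_last <- seq_len(b) * t
  if (br$has_T && !is.null(dpart$final_T)) dh_T[idx_last, ] <- dh_T[idx_last, ] + dpart$final_T
  if (br$has_L) dfinal_L <- dpart$final_L

  dH0 <- matrix(0, b * t, d)
  if (br$has_T) {
    dHt <- dh_T
    for (l in rev(seq_len(cfg$n_enc_layers)))
      dHt <- encoder_layer_bwd(dHt, cache$enc[[l]], P, G, sprintf("enc%d", l))
    dH0 <- dH0 + dHt
  }
  if (br$has_L) {
    if (is.null(dh_L)) dh_L <- matrix(0, b * t, d)
    dH0 <- dH0 + bilstm_bwd(dh_L, dfinal_L, cache$lstm, P, G)
  }

  dH <- dropout_bwd(dH0, cache$dre)
  ge <- linear_bwd(dH, cache$emb, P[["emb.W"]])
  acc_grad(G, "emb.W", ge$dW); acc_grad(G, "emb.b", ge$db)
  unflatten_batch(ge$dX, b, t)
}

# -- user-facing wrappers ----------------------------------------------------

#' Embed raw features and add positional encoding
#'
#' @param model a `wheatmoe_model`.
#' @param x `t x 10` matrix of (scaled) features for one sample.
#' @return `t x d` embedded representation (evaluation mode).
#' @export
embed_and_encode <- function(model, x) {
  if (ncol(x) != model$config$input_features)
    abort("feature count mismatch", "wheatmoe_shape_error")
  H <- add_bias(x %*% model$P[["emb.W"]], model$P[["emb.b"]])
  if (variant_branches(model$variant)$has_T)
    H <- H + positional_encoding(nrow(x), model$config$d)
  H
}

#' Transformer branch on an embedded sample
#'
#' @param model a `wheatmoe_model` with a Transformer branch.
#' @param h_emb `t x d` embedded input.
#' @return `t x d` encoder output (evaluation mode).
#' @export
transformer_branch <- function(model, h_emb) {
  cfg <- model$config
  if (is.null(model$P[["enc1.Wq"]]))
    abort("variant has no Transformer branch", "wheatmoe_config_error")
  H <- h_emb
  for (l in seq_len(cfg$n_enc_layers))
    H <- encoder_layer_fwd(H, model$P, sprintf("enc%d", l), cfg$n_heads, 1, nrow(h_emb),
                           0, FALSE)$Y
  H
}

#' Bidirectional LSTM branch on an embedded sample
#'
#' @param model a `wheatmoe_model` with an LSTM branch.
#' @param h_emb `t x d` embedded input.
#' @return list with `h_L` (`t x d` per-step outputs, forward/backward halves
#'   concatenated) and `final_L` (length-d final hidden state, last forward
#'   step then last backward step).
#' @export
lstm_branch <- function(model, h_emb) {
  cfg <- model$config
  if (is.null(model$P[["lstm1.f.W"]]))
    abort("variant has no LSTM branch", "wheatmoe_config_error")
  out <- bilstm_fwd(h_emb, model$P, cfg$lstm_layers, 1, nrow(h_emb), 0, FALSE)
  list(h_L = out$Y, final_L = drop(out$final))
}

#' Fusion head
#'
#' Concatenates the expert mixture and the two branch final states and maps
#' them through the 512 -> 256 -> 1 head (evaluation mode).
#'
#' @param model a `wheatmoe_model`.
#' @param o_moe,final_T,final_L length-d vectors (pass `NULL` for parts the
#'   variant does not have).
#' @return scalar prediction in scaled-yield units.
#' @export
fusion_head <- function(model, o_moe, final_T, final_L) {
  z <- c(o_moe, final_T, final_L)
  if (length(z) != nrow(model$P[["fus.W1"]]))
    abort("fusion input width mismatch", "wheatmoe_shape_error")
  z <- matrix(z, 1)
  h1 <- gelu(add_bias(z %*% model$P[["fus.W1"]], model$P[["fus.b1"]]))
  h2 <- gelu(add_bias(h1 %*% model$P[["fus.W2"]], model$P[["fus.b2"]]))
  drop(add_bias(h2 %*% model$P[["fus.W3"]], model$P[["fus.b3"]]))
}

#' Predict yields for samples
#'
#' @param model trained `wheatmoe_model`.
#' @param samples list of scaled [season_tensor()] (or a `[b, t, f]` array).
#' @param scaler optional fitted scaler; when given, predictions are returned
#'   in kg/ha via the inverse target transform.
#' @return numeric vector of predictions.
#' @export
predict_yield <- function(model, samples, scaler = NULL) {
  X <- if (is.array(samples) && !is.list(samples)) samples else stack_batch(samples)
  yhat <- model_forward(model, X, training = FALSE)$yhat
  if (!is.null(scaler)) yhat <- inverse_target(scaler, yhat)
  yhat
}
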