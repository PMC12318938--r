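# Composite layers: multi-head self-attention, Transformer encoder layer
# (post-norm), and a multi-layer bidirectional LSTM. Batched activations are
# stored as (b*t) x d matrices with time contiguous within each sample:
# row (i-1)*t + s holds sample i at month s.

# -- multi-head self-attention ----------------------------------------------
# No causal mask: yield estimation sees the full season context.
mha_fwd <- function(H, P, prefix, n_heads, b, t) {
  lq <- linear_fwd(H, P[[paste0(prefix, ".Wq")]], P[[paste0(prefix, ".bq")]])
  lk <- linear_fwd(H, P[[paste0(prefix, ".Wk")]], P[[paste0(prefix, ".bk")]])
  lv <- linear_fwd(H, P[[paste0(prefix, ".Wv")]], P[[paste0(prefix, ".bv")]])
  core <- mha_core_fwd(lq$Y, lk$Y, lv$Y, b, t, n_heads)
  lo <- linear_fwd(core$O, P[[paste0(prefix, ".Wo")]], P[[paste0(prefix, ".bo")]])
  list(Y = lo$Y, lq = lq, lk = lk, lv = lv, lo = lo, Pattn = core$P,
       n_heads = n_heads, b = b, t = t)
}

mha_bwd <- function(dY, cache, P, G, prefix) {
  go <- linear_bwd(dY, cache$lo, P[[paste0(prefix, ".Wo")]])
  acc_grad(G, paste0(prefix, ".Wo"), go$dW); acc_grad(G, paste0(prefix, ".bo"), go$db)
  core <- mha_core_bwd(go$dX, cache$Pattn, cache$lq$Y, cache$lk$Y, cache$lv$Y,
                       cache$b, cache$t, cache$n_heads)
  dQ <- core$dQ; dK <- core$dK; dV <- core$dV
  gq <- linear_bwd(dQ, cache$lq, P[[paste0(prefix, ".Wq")]])
  gk <- linear_bwd(dK, cache$lk, P[[paste0(prefix, ".Wk")]])
  gv <- linear_bwd(dV, cache$lv, P[[paste0(prefix, ".Wv")]])
  acc_grad(G, paste0(prefix, ".Wq"), gq$dW); acc_grad(G, paste0(prefix, ".bq"), gq$db)
  acc_grad(G, paste0(prefix, ".Wk"), gk$dW); acc_grad(G, paste0(prefix, ".bk"), gk$db)
  acc_grad(G, paste0(prefix, ".Wv"), gv$dW); acc_grad(G, paste0(prefix, ".bv"), gv$db)
  gq$dX + gk$dX + gv$dX
}

# -- encoder layer (post-norm: LN(x + sublayer(x))) --------------------------
encoder_layer_fwd <- function(H, P, prefix, n_heads, b, t, p_drop, training) {
  att <- mha_fwd(H, P, prefix, n_heads, b, t)
  dr1 <- dropout_fwd(att$Y, p_drop, training)
  ln1 <- layernorm_fwd(H + dr1$Y, P[[paste0(prefix, ".ln1.g")]], P[[paste0(prefix, ".ln1.b")]])
  f1 <- linear_fwd(ln1$Y, P[[paste0(prefix, ".ff.W1")]], P[[paste0(prefix, ".ff.b1")]])
  a1 <- gelu_fwd(f1$Y)
  f2 <- linear_fwd(a1$Y, P[[paste0(prefix, ".ff.W2")]], P[[paste0(prefix, ".ff.b2")]])
  dr2 <- dropout_fwd(f2$Y, p_drop, training)
  ln2 <- layernorm_fwd(ln1$Y + dr2$Y, P[[paste0(prefix, ".ln2.g")]], P[[paste0(prefix, ".ln2.b")]])
  list(Y = ln2$Y, att = att, dr1 = dr1, ln1 = ln1, f1 = f1, a1 = a1, f2 = f2, dr2 = dr2, ln2 = ln2)
}

encoder_layer_bwd <- function(dY, cache, P, G, prefix) {
  g2 <- layernorm_bwd(dY, cache$ln2, P[[paste0(prefix, ".ln2.g")]])
  acc_grad(G, paste0(prefix, ".ln2.g"), g2$dg); acc_grad(G, paste0(prefix, ".ln2.b"), g2$db)
  dres2 <- g2$dX
  dff <- dropout_bwd(dres2, cache$dr2)
  gf2 <- linear_bwd(dff, cache$f2, P[[paste0(prefix, ".ff.W2")]])
  acc_grad(G, paste0(prefix, ".ff.W2"), gf2$dW); acc_grad(G, paste0(prefix, ".ff.b2"), gf2$db)
  da1 <- gelu_bwd(gf2$dX, cache$a1)
  gf1 <- linear_bwd(da1, cache$f1, P[[paste0(prefix, ".ff.W1")]])
  acc_grad(G, paste0(prefix, ".ff.W1"), gf1$dW); acc_grad(G, paste0(prefix, ".ff.b1"), gf1$db)
  dln1 <- dres2 + gf1$dX
  g1 <- layernorm_bwd(dln1, cache$ln1, P[[paste0(prefix, ".ln1.g")]])
  acc_grad(G, paste0(prefix, ".ln1.g"), g1$dg); acc_grad(G, paste0(prefix, ".ln1.b"), g1$db)
  dres1 <- g1$dX
  datt <- dropout_bwd(dres1, cache$dr1)
  dH_att <- mha_bwd(datt, cache$att, P, G, prefix)
  dres1 + dH_att
}

# -- bidirectional multi-layer LSTM ------------------------------------------
# Per-direction hidden width is d/2 so that the concatenated per-step output
# keeps width d. Gate order within the 4H columns: input, forget, cell, output.
lstm_cell_fwd <- function(Xt, h_prev, c_prev, W, U, b) {
  Z <- add_bias(Xt %*% W + h_prev %*% U, b)
  Hd <- nrow(U)  # U is Hd x 4Hd
  i <- stats::plogis(Z[, 1:Hd, drop = FALSE])
  f <- stats::plogis(Z[, (Hd + 1):(2 * Hd), drop = FALSE])
  g <- tanh(Z[, (2 * Hd + 1):(3 * Hd), drop = FALSE])
  o <- stats::plogis(Z[, (3 * Hd + 1):(4 * Hd), drop = FALSE])
  c <- f * c_prev + i * g
  tc <- tanh(c)
  h <- o * tc
  list(h = h, c = c, i = i, f = f, g = g, o = o, tc = tc,
       Xt = Xt, h_prev = h_prev, c_prev = c_prev)
}

# returns gradients wrt inputs and accumulates dW, dU, db in env `acc`
lstm_cell_bwd <- function(dh, dc_in, cell, W, U, acc) {
  o <- cell$o; tc <- cell$tc; i <- cell$i; f <- cell$f; g <- cell$g
  dc <- dc_in + dh * o * (1 - tc^2)
  do <- dh * tc
  di <- dc * g
  df <- dc * cell$c_prev
  dg <- dc * i
  dzi <- di * i * (1 - i)
  dzf <- df * f * (1 - f)
  dzg <- dg * (1 - g^2)
  dzo <- do * o * (1 - o)
  dZ <- cbind(dzi, dzf, dzg, dzo)
  acc$dW <- acc$dW + crossprod(cell$Xt, dZ)
  acc$dU <- acc$dU + crossprod(cell$h_prev, dZ)
  acc$db <- acc$db + colSums(dZ)
  list(dX = dZ %*% t(W), dh_prev = dZ %*% t(U), dc_prev = dc * f)
}

# H: (b*t) x d_in. Returns per-step outputs (b*t) x d and the final hidden
# state of each direction of the top layer, concatenated (b x d).
bilstm_fwd <- function(H, P, n_layers, b, t, p_drop, training) {
  d_in <- ncol(H)
  layers <- vector("list", n_layers)
  X <- H
  for (l in seq_len(n_layers)) {
    dirs <- list()
    for (dir in c("f", "r")) {
      W <- P[[sprintf("lstm%d.%s.W", l, dir)]]
      U <- P[[sprintf("lstm%d.%s.U", l, dir)]]
      bb <- P[[sprintf("lstm%d.%s.b", l, dir)]]
      Hd <- nrow(U)
      steps <- if (dir == "f") seq_len(t) else rev(seq_len(t))
      h <- matrix(0, b, Hd); cc <- matrix(0, b, Hd)
      cells <- vector("list", t)
      out <- matrix(0, b * t, Hd)
      for (s in steps) {
        idx <- (seq_len(b) - 1L) * t + s
        cell <- lstm_cell_fwd(X[idx, , drop = FALSE], h, cc, W, U, bb)
        h <- cell$h; cc <- cell$c
        cells[[s]] <- cell
        out[idx, ] <- h
      }
      dirs[[dir]] <- list(cells = cells, out = out, final = h, steps = steps)
    }
    Y <- cbind(dirs$f$out, dirs$r$out)
    dr <- if (l < n_layers) dropout_fwd(Y, p_drop, training) else list(Y = Y, mask = NULL)
    layers[[l]] <- list(dirs = dirs, dr = dr, X = X)
    X <- dr$Y
  }
  top <- layers[[n_layers]]$dirs
  list(Y = X, final = cbind(top$f$final, top$r$final), layers = layers, b = b, t = t)
}

# dY: grad wrt per-step output; dfinal: grad wrt concat(final_f, final_r)
bilstm_bwd <- function(dY, dfinal, cache, P, G) {
  b <- cache$b; t <- cache$t
  n_layers <- length(cache$layers)
  dX_up <- dY
  for (l in rev(seq_len(n_layers))) {
    lay <- cache$layers[[l]]
    dX_up <- dropout_bwd(dX_up, lay$dr)
    Hd <- ncol(lay$dirs$f$final)
    dX_l <- matrix(0, nrow(dX_up), ncol(lay$X))
    for (dir in c("f", "r")) {
      W <- P[[sprintf("lstm%d.%s.W", l, dir)]]
      U <- P[[sprintf("lstm%d.%s.U", l, dir)]]
      acc <- new.env(parent = emptyenv())
      acc$dW <- matrix(0, nrow(W), ncol(W)); acc$dU <- matrix(0, nrow(U), ncol(U))
      acc$db <- numeric(ncol(W))
      cols <- if (dir == "f") 1:Hd else (Hd + 1):(2 * Hd)
      dh_next <- matrix(0, b, Hd); dc_next <- matrix(0, b, Hd)
      if (l == n_layers && !is.null(dfinal))
        dh_next <- dh_next + dfinal[, cols, drop = FALSE]
      dd <- lay$dirs[[dir]]
      for (s in rev(dd$steps)) {
        idx <- (seq_len(b) - 1L) * t + s
        dh <- dh_next + dX_up[idx, cols, drop = FALSE]
        gr <- lstm_cell_bwd(dh, dc_next, dd$cells[[s]], W, U, acc)
        dh_next <- gr$dh_prev; dc_next <- gr$dc_prev
        dX_l[idx, ] <- dX_l[idx, ] + gr$dX
      }
      acc_grad(G, sprintf("lstm%d.%s.W", l, dir), acc$dW)
      acc_grad(G, sprintf("lstm%d.%s.U", l, dir), acc$dU)
      acc_grad(G, sprintf("lstm%d.%s.b", l, dir), acc$db)
    }
    dX_up <- dX_l
  }
  dX_up
}
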