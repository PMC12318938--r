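# Network primitives against independent oracles, and finite-difference
# gradient checks through every variant's full forward/backward pass.

test_that("positional encoding matches a brute-force evaluation of the sinusoid", {
  PE <- positional_encoding(10, 8)
  # closed form at position 0
  expect_equal(PE[1, 1], 0)  # sin(0)
  expect_equal(PE[1, 2], 1)  # cos(0)
  # independent double-loop oracle
  oracle <- matrix(0, 10, 8)
  for (pos in 0:9) {
    for (j in 0:7) {
      i <- floor(j / 2)
      ang <- pos / 10000^(2 * i / 8)
      oracle[pos + 1, j + 1] <- if (j %% 2 == 0) sin(ang) else cos(ang)
    }
  }
  expect_equal(PE, oracle, tolerance = 1e-12)
})

test_that("attention core matches a dense R oracle and normalizes rows", {
  set.seed(5)
  b <- 2; t <- 3; h <- 2; d <- 4; hd <- d / h
  Q <- matrix(rnorm(b * t * d), b * t, d)
  K <- matrix(rnorm(b * t * d), b * t, d)
  V <- matrix(rnorm(b * t * d), b * t, d)
  core <- wheatmoe:::mha_core_fwd(Q, K, V, b, t, h)
  for (i in seq_len(b)) {
    ri <- ((i - 1) * t + 1):(i * t)
    for (hh in seq_len(h)) {
      ch <- ((hh - 1) * hd + 1):(hh * hd)
      S <- Q[ri, ch] %*% t(K[ri, ch]) / sqrt(hd)
      E <- exp(S); Pw <- E / rowSums(E)
      O_oracle <- Pw %*% V[ri, ch]
      expect_equal(core$O[ri, ch], O_oracle, tolerance = 1e-12)
      Pgot <- array(core$P, c(t, t, h * b))[, , (i - 1) * h + hh]
      expect_equal(Pgot, Pw, tolerance = 1e-12)
      expect_equal(rowSums(Pgot), rep(1, t), tolerance = 1e-12)
    }
  }
})

test_that("single-head 2x2 attention matches a hand matrix calculation", {
  # Q = [[1,0],[0,1]], K = [[1,0],[0,2]], V = [[1,2],[3,4]], scale 1/sqrt(2)
  Q <- rbind(c(1, 0), c(0, 1)); K <- rbind(c(1, 0), c(0, 2)); V <- rbind(c(1, 2), c(3, 4))
  core <- wheatmoe:::mha_core_fwd(Q, K, V, 1L, 2L, 1L)
  s2 <- 1 / sqrt(2)
  S <- rbind(c(1 * s2, 0), c(0, 2 * s2))
  P <- exp(S) / rowSums(exp(S))
  expect_equal(core$O, P %*% V, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("LSTM cell reproduces the gate equations on fixed weights", {
  Hd <- 2
  W <- matrix(0.1, 3, 4 * Hd); U <- matrix(0.05, Hd, 4 * Hd)
  b <- rep(0.2, 4 * Hd)
  Xt <- matrix(c(0.5, -0.3, 0.8), 1)
  h0 <- matrix(c(0.1, -0.2), 1); c0 <- matrix(c(0.3, 0.4), 1)
  cell <- wheatmoe:::lstm_cell_fwd(Xt, h0, c0, W, U, b)
  z <- drop(Xt %*% W + h0 %*% U) + b
  i <- plogis(z[1:2]); f <- plogis(z[3:4]); g <- tanh(z[5:6]); o <- plogis(z[7:8])
  cc <- f * c0 + i * g
  expect_equal(drop(cell$c), drop(cc), tolerance = 1e-12)
  expect_equal(drop(cell$h), drop(o * tanh(cc)), tolerance = 1e-12)
})

test_that("bidirectional symmetry: with tied weights, reversing the input swaps directions", {
  cfg <- model_config("desk", d = 8, n_heads = 2, n_enc_layers = 1, lstm_layers = 1,
                      gate_hidden = 12, fusion_dims = c(10, 6), ff_dim = 16)
  m <- build_variant("stf_moe", cfg, seed = 2)
  for (suf in c("W", "U", "b"))
    m$P[[paste0("lstm1.r.", suf)]] <- m$P[[paste0("lstm1.f.", suf)]]
  set.seed(9)
  h_emb <- matrix(rnorm(10 * 8), 10, 8)
  fwd <- lstm_branch(m, h_emb)
  rev_out <- lstm_branch(m, h_emb[10:1, ])
  expect_equal(rev_out$h_L[10:1, 5:8], fwd$h_L[, 1:4], tolerance = 1e-12)
  expect_equal(rev_out$h_L[10:1, 1:4], fwd$h_L[, 5:8], tolerance = 1e-12)
})

test_that("analytic gradients match finite differences in every variant", {
  cfg <- tiny_config()
  for (variant in c("stf_moe", "stf_moe_dense", "stf_single_expert",
                    "stf_no_moe", "lstm", "transformer", "lstm_transformer")) {
    m <- build_variant(variant, cfg, seed = 3)
    set.seed(42)
    b <- 3
    X <- random_sample_array(b, seed = 42)
    y <- rnorm(b)
    lossfn <- function() {
      huber_loss(y, wheatmoe:::model_forward(m, X, training = FALSE)$yhat, 1.0)
    }
    fw <- wheatmoe:::model_forward(m, X, training = FALSE)
    wheatmoe:::zero_grads(m)
    dX <- wheatmoe:::model_backward(m, fw$cache, wheatmoe:::huber_grad(y, fw$yhat, 1.0))
    eps <- 1e-5
    for (nm in ls(m$P)) {
      v <- m$P[[nm]]
      for (ii in sample(length(v), min(2, length(v)))) {
        g_an <- if (is.null(m$G[[nm]])) 0 else m$G[[nm]][ii]
        m$P[[nm]][ii] <- v[ii] + eps; lp <- lossfn()
        m$P[[nm]][ii] <- v[ii] - eps; lm <- lossfn()
        m$P[[nm]][ii] <- v[ii]
        expect_lt(rel_err(g_an, (lp - lm) / (2 * eps)), 1e-3,
                  label = sprintf("%s gradient of %s[%d]", variant, nm, ii))
      }
    }
    # input gradients (used by the attribution module)
    for (ii in sample(length(X), 4)) {
      xv <- X[ii]
      X[ii] <- xv + eps; lp <- lossfn()
      X[ii] <- xv - eps; lm <- lossfn()
      X[ii] <- xv
      expect_lt(rel_err(dX[ii] * 1, (lp - lm) / (2 * eps)) , 1e-3,
                label = sprintf("%s input gradient", variant))
    }
  }
})

test_that("evaluation-mode forward passes are bitwise deterministic", {
  m <- build_variant("stf_moe", tiny_config(), seed = 4)
  X <- random_sample_array(4, seed = 7)
  y1 <- wheatmoe:::model_forward(m, X)$yhat
  y2 <- wheatmoe:::model_forward(m, X)$yhat
  expect_identical(y1, y2)
})

test_that("month order matters to both branches", {
  m <- build_variant("stf_moe", tiny_config(), seed = 5)
  set.seed(11)
  x <- matrix(rnorm(100), 10, 10)
  h <- embed_and_encode(m, x)
  h_shuf <- embed_and_encode(m, x[c(2:10, 1), ])
  expect_false(isTRUE(all.equal(transformer_branch(m, h)[10, ],
                                transformer_branch(m, h_shuf)[10, ])))
  expect_false(isTRUE(all.equal(lstm_branch(m, h)$final_L,
                                lstm_branch(m, h_shuf)$final_L)))
})
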