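# Gating, expert pool, mixture, fusion head, variants, FLOP accounting.

forced_gate_params <- function(g_target, d = 8, gh = 12) {
  # zero weights route everything through b2, so softmax(b2) = g_target
  list(W1 = matrix(0, 2 * d, gh), b1 = numeric(gh),
       W2 = matrix(0, gh, 5), b2 = log(g_target))
}

test_that("gate is uniform under zero parameters and selects Top-2 unnormalized", {
  d <- 8
  h <- matrix(rnorm(10 * 2 * d), 10, 2 * d)
  dec <- gate_decision(h, list(W1 = matrix(0, 2 * d, 12), b1 = numeric(12),
                               W2 = matrix(0, 12, 5), b2 = numeric(5)))
  expect_equal(dec$g, rep(0.2, 5))
  expect_identical(dec$epsilon, c(0L, 1L))  # tie broken by lowest index

  g <- c(0.5, 0.3, 0.1, 0.06, 0.04)
  dec <- gate_decision(h, forced_gate_params(g))
  expect_equal(dec$g, g, tolerance = 1e-12)
  expect_identical(dec$epsilon, c(0L, 1L))
  expect_equal(dec$w, c(0.5, 0.3), tolerance = 1e-12)  # NOT renormalized

  g_tie <- c(0.25, 0.25, 0.25, 0.125, 0.125)
  dec <- gate_decision(h, forced_gate_params(g_tie))
  expect_identical(dec$epsilon, c(0L, 1L))

  expect_error(gate_decision(matrix(NaN, 2, 2 * d), forced_gate_params(g)),
               class = "wheatmoe_nonfinite")
})

test_that("gate probabilities sum to one for random inputs and parameters", {
  set.seed(13)
  d <- 8
  P <- list("gate.W1" = matrix(rnorm(2 * d * 12, sd = 0.5), 2 * d, 12),
            "gate.b1" = rnorm(12), "gate.W2" = matrix(rnorm(12 * 5, sd = 0.5), 12, 5),
            "gate.b2" = rnorm(5))
  gb <- wheatmoe:::gate_batch(matrix(rnorm(500 * 2 * d), 500, 2 * d), P, 2L)
  expect_true(all(abs(rowSums(gb$g) - 1) < 1e-6))
  expect_true(all(gb$g >= 0))
})

test_that("each expert matches an independent layer-by-layer re-evaluation", {
  d <- 8
  m <- build_variant("stf_moe", tiny_config(), seed = 6)
  set.seed(20)
  x <- rnorm(2 * d)
  # independent oracle: resolved expert table re-evaluated with plain code
  gelu_ <- function(z) z * pnorm(z)
  silu_ <- function(z) z * plogis(z)
  relu_ <- function(z) pmax(z, 0)
  lin <- function(v, e, l) drop(v %*% m$P[[sprintf("exp%d.W%d", e, l)]]) +
    m$P[[sprintf("exp%d.b%d", e, l)]]
  oracle <- list(
    function(v) gelu_(lin(gelu_(lin(v, 0, 1)), 0, 2)),
    function(v) lin(relu_(lin(v, 1, 1)), 1, 2),
    function(v) silu_(lin(silu_(lin(v, 2, 1)), 2, 2)),
    function(v) gelu_(lin(v, 3, 1)),
    function(v) lin(relu_(lin(relu_(lin(v, 4, 1)), 4, 2)), 4, 3))
  widths <- c(d, d, d / 2, d, d)
  for (e in 0:4) {
    out <- expert_forward(m, e, x)
    expect_length(out, widths[e + 1])
    expect_equal(out, oracle[[e + 1]](x), tolerance = 1e-12,
                 label = sprintf("expert %d", e))
    expect_identical(out, expert_forward(m, e, x))  # eval-mode determinism
  }
  expect_error(expert_forward(m, 7, x), class = "wheatmoe_config_error")
})

test_that("expert 3 with identity-like weights is an element-wise GELU", {
  d <- 8
  m <- build_variant("stf_moe", tiny_config(), seed = 7)
  m$P[["exp3.W1"]] <- rbind(diag(d), matrix(0, d, d))
  m$P[["exp3.b1"]] <- numeric(d)
  x <- c(seq(-2, 2, length.out = d), rep(9, d))  # second half projected away
  expect_equal(expert_forward(m, 3, x), seq(-2, 2, length.out = d) * pnorm(seq(-2, 2, length.out = d)))
})

test_that("sparse mixture evaluates exactly k experts and is linear in weights", {
  m <- build_variant("stf_moe", tiny_config(), seed = 8)
  set.seed(21)
  h <- matrix(rnorm(10 * 16), 10, 16)
  wheatmoe:::reset_counter(m)
  out <- moe_forward(m, h)
  expect_identical(m$counter$calls, 2L)
  dec <- out$decision
  # dense oracle: adapt every expert, zero the non-selected weights
  h_avg <- colMeans(h)
  adapted <- vapply(0:4, function(e) {
    drop(expert_forward(m, e, h_avg) %*% m$P[[sprintf("exp%d.Wa", e)]]) +
      m$P[[sprintf("exp%d.ba", e)]]
  }, numeric(m$config$d))
  w_full <- numeric(5); w_full[dec$epsilon + 1] <- dec$w
  expect_equal(out$o_moe, drop(adapted %*% w_full), tolerance = 1e-9)
})

test_that("fusion head is affine in its bias and matches hand evaluation", {
  cfg <- tiny_config()
  m <- build_variant("stf_moe", cfg, seed = 9)
  d <- cfg$d
  for (nm in c("fus.W1", "fus.W2", "fus.W3")) m$P[[nm]][] <- 0
  m$P[["fus.b3"]] <- 0.37
  expect_equal(fusion_head(m, rnorm(d), rnorm(d), rnorm(d)), 0.37)
  # tiny hand evaluation
  m2 <- build_variant("stf_moe", cfg, seed = 10)
  z <- rnorm(3 * d)
  h1 <- z %*% m2$P[["fus.W1"]] + rep(m2$P[["fus.b1"]], each = 1)
  h1 <- h1 * pnorm(h1)
  h2 <- h1 %*% m2$P[["fus.W2"]] + rep(m2$P[["fus.b2"]], each = 1)
  h2 <- h2 * pnorm(h2)
  expect_equal(fusion_head(m2, z[1:d], z[(d + 1):(2 * d)], z[(2 * d + 1):(3 * d)]),
               drop(h2 %*% m2$P[["fus.W3"]]) + m2$P[["fus.b3"]], tolerance = 1e-12)
  expect_error(fusion_head(m2, rnorm(3), rnorm(3), rnorm(3)), class = "wheatmoe_shape_error")
})

test_that("variants build, produce finite outputs, and enforce contracts", {
  X <- stack_batch(apply_scaler(fit_scaler(fixture_dataset()$samples),
                                fixture_dataset()$samples[1:6]))
  for (v in wheatmoe:::MODEL_VARIANTS) {
    m <- build_variant(v, tiny_config(), seed = 11)
    yhat <- wheatmoe:::model_forward(m, X)$yhat
    expect_length(yhat, 6L)
    expect_true(all(is.finite(yhat)), label = v)
  }
  expect_error(build_variant("mlp", tiny_config()), class = "wheatmoe_config_error")

  m <- build_variant("stf_single_expert", tiny_config(), seed = 12)
  wheatmoe:::reset_counter(m)
  wheatmoe:::model_forward(m, X)
  expect_identical(m$counter$calls, 6L)            # one expert call per sample
  expect_identical(m$counter$per_expert[1], 6)     # always expert 0
})

test_that("near-one-hot gating makes dense and sparse variants agree", {
  cfg <- tiny_config()
  sparse <- build_variant("stf_moe", cfg, seed = 13)
  dense <- build_variant("stf_moe_dense", cfg, seed = 13)  # identical init
  for (mm in list(sparse, dense)) {
    mm$P[["gate.W1"]][] <- 0; mm$P[["gate.W2"]][] <- 0
    mm$P[["gate.b1"]][] <- 0
    mm$P[["gate.b2"]] <- c(60, 0, -60, -60, -60)  # expert 0 takes all the mass
  }
  X <- random_sample_array(3, seed = 14)
  y1 <- wheatmoe:::model_forward(sparse, X)$yhat
  y2 <- wheatmoe:::model_forward(dense, X)$yhat
  expect_equal(y1, y2, tolerance = 1e-8)
})

test_that("FLOP accounting follows the 2mn convention and expected orderings", {
  expect_identical(wheatmoe:::dense_flops(10, 128), 2560)
  # manual tally for a 2-layer expert MLP: expert 3 is 2d -> d plus adapter d -> d
  d <- 32
  expect_identical(wheatmoe:::expert_flops(3, d), 2 * (2 * d) * d + 2 * d * d)
  cfg <- model_config("desk")
  f_sparse <- count_flops(build_variant("stf_moe", cfg, seed = 1))
  f_dense <- count_flops(build_variant("stf_moe_dense", cfg, seed = 1))
  f_none <- count_flops(build_variant("stf_no_moe", cfg, seed = 1))
  f_single <- count_flops(build_variant("stf_single_expert", cfg, seed = 1))
  expect_gt(f_dense, f_sparse)
  expect_gt(f_sparse, f_none)
  expect_gt(f_dense, f_single)
})

test_that("model checkpoints round-trip through JSON", {
  m <- build_variant("stf_moe", tiny_config(), seed = 15)
  X <- random_sample_array(2, seed = 16)
  y1 <- wheatmoe:::model_forward(m, X)$yhat
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$variant, "stf_moe")
  expect_equal(wheatmoe:::model_forward(m2, X)$yhat, y1, tolerance = 1e-12)
})
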