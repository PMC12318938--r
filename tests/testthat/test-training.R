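# Loss, splits, the training loop, and the evaluation protocols.

test_that("Huber loss covers both branches and validates delta", {
  expect_equal(huber_loss(1, 1), 0)
  expect_equal(huber_loss(0, 0.5, delta = 1), 0.125)   # quadratic branch
  expect_equal(huber_loss(0, 2, delta = 1), 1.5)       # linear branch
  expect_equal(huber_loss(c(0, 0), c(0.5, 2)), mean(c(0.125, 1.5)))
  expect_error(huber_loss(1, 1, delta = 0), class = "wheatmoe_invalid_argument")
})

test_that("fixed-year split partitions samples 8:2 with disjoint keys", {
  ds <- fixture_dataset()
  sp <- fixed_year_split(ds$samples, 2021, seed = 3)
  expect_length(c(sp$train, sp$val, sp$test), 40L)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_true(all(vapply(ds$samples[sp$test], `[[`, integer(1), "year") == 2021))
  non_test <- length(sp$train) + length(sp$val)
  expect_lte(abs(length(sp$val) - 0.2 * non_test), 1)
  expect_error(fixed_year_split(ds$samples, 1999), class = "wheatmoe_invalid_argument")
})

test_that("training reduces the loss, clips gradients, and logs data access", {
  ds <- fixture_dataset()
  sp <- fixed_year_split(ds$samples, 2021, seed = 1)
  m <- build_variant("stf_moe", tiny_config(), seed = 1)
  cfg <- train_config("desk", epochs = 50, seed = 1)
  fit <- train(m, ds$samples, sp, cfg)
  h <- fit$history
  expect_identical(nrow(h), 50L)
  expect_lt(h$train_loss[50], h$train_loss[1])
  expect_true(all(fit$grad_norms <= cfg$grad_clip + 1e-6))
  # leakage audit: neither the scaler nor the optimizer saw test-year keys
  test_keys <- dataset_keys(ds$samples[sp$test])
  expect_length(intersect(fit$access_log$scaler_keys, test_keys), 0L)
  expect_length(intersect(fit$access_log$train_keys, test_keys), 0L)
  expect_setequal(fit$access_log$scaler_keys, fit$access_log$train_keys)
})

test_that("training is deterministic under a fixed seed", {
  ds <- fixture_dataset()
  sp <- fixed_year_split(ds$samples, 2021, seed = 2)
  run <- function() {
    m <- build_variant("stf_moe", tiny_config(), seed = 5)
    fit <- train(m, ds$samples, sp, train_config("desk", epochs = 5, seed = 9))
    fit$history$val_loss
  }
  expect_identical(run(), run())
})

test_that("zero learning rate leaves parameters and loss unchanged", {
  ds <- fixture_dataset()
  sp <- fixed_year_split(ds$samples, 2021, seed = 2)
  m <- build_variant("stf_moe", tiny_config(), seed = 6)
  before <- wheatmoe:::copy_params(m)
  fit <- train(m, ds$samples, sp, train_config("desk", epochs = 3, lr = 0, seed = 1))
  for (nm in names(before)) expect_identical(m$P[[nm]], before[[nm]])
  expect_equal(fit$history$val_loss, rep(fit$history$val_loss[1], 3))
})

test_that("empty splits are rejected", {
  ds <- fixture_dataset()
  m <- build_variant("stf_moe", tiny_config(), seed = 1)
  expect_error(train(m, ds$samples, list(train = integer(0), val = 1:3)),
               class = "wheatmoe_invalid_argument")
})

test_that("rolling protocol emits one row per year plus a mean row", {
  ds <- fixture_dataset()
  res <- rolling_protocol(ds$samples, function(s) build_variant("stf_moe", tiny_config(), seed = s),
                          train_config("desk", epochs = 3, seed = 0))
  expect_identical(nrow(res), 6L)  # 5 years + mean
  expect_equal(res$r2[6], mean(res$r2[1:5]))
  expect_equal(res$rmse[6], mean(res$rmse[1:5]))
  one_year <- Filter(function(s) s$year == 2017, ds$samples)
  expect_error(rolling_protocol(one_year, function(s) NULL),
               class = "wheatmoe_invalid_argument")  # single year
})

test_that("progressive evaluation returns one row per cutoff month", {
  ds <- fixture_dataset()
  res <- progressive_monthly_eval(ds$samples, months = c(4, 10),
                                  function(s) build_variant("stf_moe", tiny_config(), seed = s),
                                  train_config("desk", epochs = 3, seed = 0))
  expect_identical(nrow(res), 2L)
  expect_identical(res$month, c(4, 10))
  expect_true(all(is.finite(res$r2)))
})

test_that("ablation reports all four variants with FLOPs", {
  ds <- fixture_dataset()
  sp <- fixed_year_split(ds$samples, 2021, seed = 4)
  res <- ablate(ds$samples, sp, config = tiny_config(),
                cfg = train_config("desk", epochs = 2, seed = 0))
  expect_identical(res$variant, c("stf_moe", "stf_no_moe", "stf_single_expert", "stf_moe_dense"))
  expect_true(all(is.finite(res$r2)))
  expect_gt(res$flops[res$variant == "stf_moe_dense"], res$flops[res$variant == "stf_moe"])
})
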