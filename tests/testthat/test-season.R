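# Season assembly, gap filling, truncation, and min-max scaling.

make_records <- function(months = 1:10, seed = 1) {
  set.seed(seed)
  df <- data.frame(month_index = months)
  for (f in wheatmoe:::FEATURES) df[[f]] <- runif(length(months))
  df$DEM <- 750; df$SoC <- 11.5
  df
}

test_that("complete records pass through unchanged and assembly is idempotent", {
  rec <- make_records()
  s <- assemble_season(rec, "A", 2020, y = 5000)
  expect_s3_class(s, "season_tensor")
  expect_identical(dim(s$x), c(10L, 10L))
  expect_equal(unname(s$x[, "NDVI"]), rec$NDVI)
  # idempotence: re-assembling the assembled values reproduces them
  rec2 <- data.frame(month_index = 1:10, s$x, check.names = FALSE)
  s2 <- assemble_season(rec2, "A", 2020, y = 5000)
  expect_equal(s2$x, s$x)
})

test_that("interior gaps interpolate linearly and ends extend nearest values", {
  rec <- make_records(months = c(1, 2, 3, 4, 6, 7, 8, 9, 10))  # month 5 missing
  s <- assemble_season(rec, "A", 2020)
  expect_equal(unname(s$x[5, "NDVI"]), (rec$NDVI[4] + rec$NDVI[5]) / 2)
  rec_end <- make_records(months = 2:10)  # September missing
  s2 <- assemble_season(rec_end, "A", 2020)
  expect_equal(unname(s2$x[1, "EVI"]), rec_end$EVI[1])
})

test_that("sparse coverage is rejected and static columns broadcast", {
  rec <- make_records(months = c(1, 3, 5, 7, 9))  # 5 months only
  expect_error(assemble_season(rec, "A", 2020), class = "wheatmoe_insufficient_coverage")
  s <- assemble_season(make_records(), "A", 2020)
  expect_true(all(s$x[, "DEM"] == s$x[1, "DEM"]))
  expect_true(all(s$x[, "SoC"] == s$x[1, "SoC"]))
})

test_that("truncate_to_month slices leading months and validates m", {
  s <- assemble_season(make_records(), "A", 2020, y = 4000)
  expect_equal(truncate_to_month(s, 10)$x, s$x)
  expect_identical(nrow(truncate_to_month(s, 1)$x), 1L)
  # independent slice oracle
  s7 <- truncate_to_month(s, 7)
  expect_equal(s7$x, s$x[1:7, ])
  expect_identical(s7$y, s$y)
  expect_error(truncate_to_month(s, 0), class = "wheatmoe_invalid_argument")
  expect_error(truncate_to_month(s, 11), class = "wheatmoe_invalid_argument")
})

test_that("min-max scaler maps train to [0,1], allows out-of-range test values, inverts", {
  mk <- function(v, y) season_tensor("A", 2000 + v, matrix(v, 10, 10), y)
  train <- lapply(c(2, 4, 6), function(v) mk(v, 1000 * v))
  sc <- fit_scaler(train)
  tr <- apply_scaler(sc, train)
  expect_equal(unname(tr[[1]]$x[1, 1]), 0)
  expect_equal(unname(tr[[2]]$x[1, 1]), 0.5)
  expect_equal(unname(tr[[3]]$x[1, 1]), 1)
  te <- apply_scaler(sc, list(mk(8, 9000)))
  expect_equal(unname(te[[1]]$x[1, 1]), 1.5)
  y <- c(2100, 4400, 6100)
  expect_equal(inverse_target(sc, scale_target(sc, y)), y, tolerance = 1e-9)
  expect_error(apply_scaler(structure(list(fitted = FALSE), class = "minmax_scaler"), train),
               class = "wheatmoe_not_fitted")
})

test_that("scaler parameters come from the training split only (leakage sentinel)", {
  ds <- fixture_dataset()
  train <- ds$samples[1:30]
  test <- ds$samples[31:40]
  # inject an extreme value into the test split; a leaking scaler would move
  test[[1]]$x[1, "NDVI"] <- 99
  sc_train <- fit_scaler(train)
  sc_leak <- fit_scaler(c(train, test))
  expect_lt(sc_train$feature_max["NDVI"], 2)
  expect_equal(unname(sc_leak$feature_max["NDVI"]), 99)
  expect_false(isTRUE(all.equal(sc_train$feature_max, sc_leak$feature_max)))
  # transforming test data with train parameters leaves the sentinel out of range
  scaled <- apply_scaler(sc_train, test)
  expect_gt(max(scaled[[1]]$x[, "NDVI"]), 1)
})

test_that("scaler serialization round-trips", {
  ds <- fixture_dataset()
  sc <- fit_scaler(ds$samples[1:20])
  path <- tempfile(fileext = ".json")
  write_scaler(sc, path)
  sc2 <- read_scaler(path)
  expect_equal(sc2$feature_min, sc$feature_min)
  expect_equal(sc2$feature_max, sc$feature_max)
  expect_equal(sc2$y_min, sc$y_min)
  y <- c(3000, 5000)
  expect_equal(inverse_target(sc2, scale_target(sc2, y)), y)
})
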