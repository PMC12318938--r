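# Synthetic county-year generator. It emulates the statistical structure the
# downstream analysis assumes: a shared latent NDVI green-up/senescence curve
# driving the correlated vegetation-index family, seasonal meteorology with
# county offsets, static terrain/soil covariates drawn once per county, and a
# yield response that is linear in season summaries of the (scaled) features
# with signed effects: negative for RHum, DEM, SoC; positive for Fpar, NIRv,
# Rad. Yields are in kg/ha and truncated at a positive floor.

# Nominal center/scale used to standardize season summaries inside the latent
# yield function (approximately the summary mean/sd under default settings, so
# effect-vector entries read as "kg/ha per typical-variation unit").
EFFECT_CENTER <- c(NDVI = 0.38, EVI = 0.29, NIRv = 0.16, Red = 0.21, LAI = 2.0,
                   Fpar = 0.40, RHum = 60, Rad = 350, DEM = 900, SoC = 12)
EFFECT_SCALE <- c(NDVI = 0.035, EVI = 0.03, NIRv = 0.015, Red = 0.008, LAI = 0.3,
                  Fpar = 0.04, RHum = 8, Rad = 30, DEM = 450, SoC = 4)

#' Configuration of the synthetic data generator
#'
#' Defaults encode the world the package's tests assume: 10-month seasons, a
#' logistic-bell NDVI trajectory peaking in April (month 8 of the
#' September-indexed season), strongly correlated vegetation indices, and a
#' yield function whose dominant driver is relative humidity with a negative
#' sign, followed by elevation (negative) and canopy light absorption
#' (positive).
#'
#' @param n_counties number of counties (> 0).
#' @param years inclusive integer vector of harvest years (non-empty).
#' @param seed integer seed; identical config + seed gives identical data.
#' @param vi_curve list with `peak` (month of NDVI maximum), `amplitude`,
#'   `width` (months), `base` (off-season NDVI).
#' @param noise_sd named per-feature observation noise, feature units.
#' @param effect_vector named signed coefficients of the latent yield function,
#'   kg/ha per scaled summary unit.
#' @param yield_base mean yield, kg/ha.
#' @param yield_noise_sd yield noise, kg/ha.
#' @param yield_floor positive truncation floor, kg/ha.
#' @param effect_timing `"season"`: summaries are full-season means;
#'   `"late"`: summaries use months 8-10 only and relative humidity receives a
#'   county-year late-season anomaly, making the signal largely invisible
#'   before spring (used to probe progressive in-season evaluation).
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(n_counties = 100L,
                             years = 2012:2021,
                             seed = 0L,
                             vi_curve = list(peak = 8, amplitude = 0.45, width = 2, base = 0.18),
                             noise_sd = c(NDVI = 0.02, EVI = 0.02, NIRv = 0.015, Red = 0.01,
                                          LAI = 0.25, Fpar = 0.03, RHum = 2, Rad = 15,
                                          DEM = 0, SoC = 0),
                             effect_vector = c(NDVI = 100, EVI = 80, NIRv = 250, Red = -50,
                                               LAI = 100, Fpar = 300, RHum = -600, Rad = 150,
                                               DEM = -300, SoC = -150),
                             yield_base = 5500,
                             yield_noise_sd = 150,
                             yield_floor = 100,
                             effect_timing = c("season", "late")) {
  if (length(n_counties) != 1 || is.na(n_counties) || n_counties < 1)
    abort("n_counties must be a positive integer", "wheatmoe_invalid_config")
  if (length(years) == 0) abort("year range must be non-empty", "wheatmoe_invalid_config")
  noise_sd <- noise_sd[FEATURES]; effect_vector <- effect_vector[FEATURES]
  if (any(is.na(noise_sd)) || any(noise_sd < 0))
    abort("noise_sd must be named, complete and >= 0", "wheatmoe_invalid_config")
  if (any(is.na(effect_vector))) abort("effect_vector incomplete", "wheatmoe_invalid_config")
  if (yield_noise_sd < 0 || yield_base <= 0 || yield_floor <= 0)
    abort("yield parameters must be positive (noise >= 0)", "wheatmoe_invalid_config")
  structure(list(n_counties = as.integer(n_counties), years = as.integer(years),
                 season_length = SEASON_LENGTH, seed = as.integer(seed),
                 vi_curve = vi_curve, noise_sd = noise_sd, effect_vector = effect_vector,
                 yield_base = yield_base, yield_noise_sd = yield_noise_sd,
                 yield_floor = yield_floor, effect_timing = match.arg(effect_timing)),
            class = "synthetic_config")
}

#' Generate a synthetic county-year dataset
#'
#' Each county draws static DEM (lognormal, metres) and SoC (truncated normal,
#' g/kg) once, plus persistent offsets for relative humidity, radiation, and a
#' vegetation-amplitude factor. Each county-year perturbs the NDVI amplitude;
#' EVI, NIRv, Red, LAI and Fpar are monotone transforms of the latent NDVI
#' trajectory plus independent noise, so the index family is strongly
#' collinear by construction. Yield is the latent linear function of scaled
#' season summaries plus Gaussian noise, truncated at the positive floor.
#'
#' @param config a [synthetic_config()].
#' @return `synthetic_dataset`: list with `samples` (list of
#'   [season_tensor()]) and `truth` (the latent parameters used).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  set.seed(config$seed)
  vc <- config$vi_curve
  mns <- seq_len(SEASON_LENGTH)
  bell <- exp(-(mns - vc$peak)^2 / (2 * vc$width^2))
  late <- config$effect_timing == "late"
  window <- if (late) 8:10 else mns

  nC <- config$n_counties
  county_ids <- sprintf("C%03d", seq_len(nC))
  dem <- pmin(pmax(exp(stats::rnorm(nC, log(800), 0.5)), 50), 4000)
  soc <- pmin(pmax(stats::rnorm(nC, 12, 4), 2), 30)
  amp_factor <- stats::rnorm(nC, 1, 0.15)
  rhum_off <- stats::rnorm(nC, 0, 8)
  rad_off <- stats::rnorm(nC, 0, 30)

  rh_season <- 10 * cos(2 * pi * (mns - 4.5) / 12)
  rad_season <- 420 - 180 * exp(-(mns - 4.5)^2 / 6)
  ns <- config$noise_sd
  ev <- config$effect_vector

  samples <- vector("list", nC * length(config$years))
  k <- 0L
  for (ci in seq_len(nC)) {
    for (yr in config$years) {
      amp <- vc$amplitude * amp_factor[ci] * (1 + stats::rnorm(1, 0, 0.08))
      lat <- pmin(pmax(vc$base + amp * bell, 0.02), 0.95)
      rh_anom <- if (late) stats::rnorm(1, 0, 6) else 0

      x <- matrix(0, SEASON_LENGTH, length(FEATURES), dimnames = list(MONTH_LABELS, FEATURES))
      x[, "NDVI"] <- lat + stats::rnorm(SEASON_LENGTH, 0, ns["NDVI"])
      x[, "EVI"] <- 0.9 * lat - 0.05 + stats::rnorm(SEASON_LENGTH, 0, ns["EVI"])
      x[, "NIRv"] <- lat * (0.15 + 0.35 * lat) + stats::rnorm(SEASON_LENGTH, 0, ns["NIRv"])
      x[, "Red"] <- 0.30 - 0.22 * lat + stats::rnorm(SEASON_LENGTH, 0, ns["Red"])
      x[, "LAI"] <- 6.5 * lat^1.8 + stats::rnorm(SEASON_LENGTH, 0, ns["LAI"])
      x[, "Fpar"] <- pmin(pmax(1.24 * lat - 0.07, 0), 0.98) + stats::rnorm(SEASON_LENGTH, 0, ns["Fpar"])
      x[, "RHum"] <- pmin(pmax(60 + rh_season + rhum_off[ci] + rh_anom * (mns >= 8) +
                                 stats::rnorm(SEASON_LENGTH, 0, ns["RHum"]), 5), 100)
      x[, "Rad"] <- pmax(rad_season + rad_off[ci] + stats::rnorm(SEASON_LENGTH, 0, ns["Rad"]), 0)
      x[, "DEM"] <- dem[ci] + if (ns["DEM"] > 0) stats::rnorm(1, 0, ns["DEM"]) else 0
      x[, "SoC"] <- soc[ci] + if (ns["SoC"] > 0) stats::rnorm(1, 0, ns["SoC"]) else 0

      y <- latent_yield(x, config, window) + stats::rnorm(1, 0, config$yield_noise_sd)
      y <- max(y, config$yield_floor)
      k <- k + 1L
      samples[[k]] <- season_tensor(county_ids[ci], yr, x, y)
    }
  }
  structure(list(samples = samples,
                 truth = list(effect_vector = ev, effect_window = window,
                              center = EFFECT_CENTER, scale = EFFECT_SCALE,
                              yield_base = config$yield_base, dem = dem, soc = soc),
                 config = config),
            class = "synthetic_dataset")
}

# The latent yield function: yield_base + sum_j beta_j * z_j where z_j is the
# standardized window-mean of feature j (static features are constant so the
# window is immaterial for them).
latent_yield <- function(x, config, window = seq_len(SEASON_LENGTH)) {
  s <- colMeans(x[window, , drop = FALSE])
  z <- (s - EFFECT_CENTER) / EFFECT_SCALE
  config$yield_base + sum(config$effect_vector * z)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d samples (%d counties x %d years), seed %d\n",
              length(x$samples), x$config$n_counties, length(x$config$years), x$config$seed))
  invisible(x)
}

#' Tiny deterministic fixture dataset
#'
#' 8 counties by 5 years (40 samples) with default structure, for unit tests
#' and smoke runs. Optionally written to the county-year CSV schema.
#'
#' @param seed integer seed.
#' @param path optional CSV path to write the dataset to.
#' @return a `synthetic_dataset` (invisibly returns it when `path` is given).
#' @export
make_fixture <- function(seed = 0L, path = NULL) {
  cfg <- synthetic_config(n_counties = 8L, years = 2017:2021, seed = seed)
  ds <- generate_dataset(cfg)
  if (!is.null(path)) {
    write_county_table(ds$samples, path)
    return(invisible(ds))
  }
  ds
}
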