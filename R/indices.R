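# Spectral indices and relative humidity, vectorized over reflectance /
# temperature inputs. Reflectances are surface reflectance in [0, 1]; a small
# tolerance above 1 is accepted because composited products occasionally
# overshoot.

check_reflectance <- function(..., what = "reflectance") {
  for (x in list(...)) {
    if (any(!is.na(x) & (x < 0 | x > 1.2)))
      abort(sprintf("%s outside [0, 1.2]", what), "wheatmoe_invalid_input")
  }
}

#' Normalized difference vegetation index
#'
#' `NDVI = (rho_NIR - rho_Red) / (rho_NIR + rho_Red)`.
#'
#' @param rho_nir,rho_red near-infrared and red surface reflectance.
#' @return NDVI in `[-1, 1]`.
#' @export
compute_ndvi <- function(rho_nir, rho_red) {
  check_reflectance(rho_nir, rho_red)
  den <- rho_nir + rho_red
  if (any(!is.na(den) & den <= 0))
    abort("NDVI undefined: rho_NIR + rho_Red must be > 0", "wheatmoe_undefined_index")
  (rho_nir - rho_red) / den
}

#' Near-infrared reflectance of vegetation
#'
#' `NIRv = rho_NIR * NDVI`, the product of near-infrared reflectance and NDVI;
#' suppresses the non-photosynthetic background signal and tracks canopy
#' photosynthetic capacity.
#'
#' @inheritParams compute_ndvi
#' @return NIRv (dimensionless).
#' @export
compute_nirv <- function(rho_nir, rho_red) {
  rho_nir * compute_ndvi(rho_nir, rho_red)
}

#' Enhanced vegetation index
#'
#' Standard MODIS parameterization
#' `EVI = 2.5 (N - R) / (N + 6 R - 7.5 B + 1)` with gain 2.5, aerosol
#' coefficients 6 and 7.5 on the red and blue bands, and canopy background
#' adjustment 1.
#'
#' @inheritParams compute_ndvi
#' @param rho_blue blue surface reflectance (required).
#' @return EVI (dimensionless, finite).
#' @export
compute_evi <- function(rho_nir, rho_red, rho_blue) {
  if (missing(rho_blue) || is.null(rho_blue) || any(is.na(rho_blue)))
    abort("EVI requires the blue band", "wheatmoe_invalid_input")
  check_reflectance(rho_nir, rho_red, rho_blue)
  den <- rho_nir + 6 * rho_red - 7.5 * rho_blue + 1
  if (any(!is.na(den) & abs(den) < 1e-12))
    abort("EVI undefined: zero denominator", "wheatmoe_undefined_index")
  2.5 * (rho_nir - rho_red) / den
}

#' Green normalized difference vegetation index
#'
#' `GNDVI = (rho_NIR - rho_Green) / (rho_NIR + rho_Green)`; the green band
#' replaces red to avoid NDVI's saturation at high biomass.
#'
#' @inheritParams compute_ndvi
#' @param rho_green green surface reflectance.
#' @return GNDVI in `[-1, 1]`.
#' @export
compute_gndvi <- function(rho_nir, rho_green) {
  check_reflectance(rho_nir, rho_green)
  den <- rho_nir + rho_green
  if (any(!is.na(den) & den <= 0))
    abort("GNDVI undefined: rho_NIR + rho_Green must be > 0", "wheatmoe_undefined_index")
  (rho_nir - rho_green) / den
}

# Magnus saturation-vapour-pressure constants (Alduchov-Eskridge fit).
MAGNUS_A <- 17.625
MAGNUS_B <- 243.04

#' Relative humidity from air and dewpoint temperature
#'
#' Magnus approximation: `RH = 100 * es(Td) / es(T)` with
#' `es(T) = exp(a T / (b + T))` up to a common factor, `a = 17.625`,
#' `b = 243.04` degC. Result is clipped to `(0, 100]`; dewpoint more than
#' 0.5 degC above air temperature is rejected as physically inconsistent.
#'
#' @param t2m 2 m air temperature, degC.
#' @param td2m 2 m dewpoint temperature, degC.
#' @return relative humidity in percent.
#' @export
relative_humidity_magnus <- function(t2m, td2m) {
  stopifnot_finite(t2m, "t2m"); stopifnot_finite(td2m, "td2m")
  if (any(td2m > t2m + 0.5))
    abort("dewpoint exceeds air temperature beyond tolerance", "wheatmoe_invalid_input")
  rh <- 100 * exp(MAGNUS_A * td2m / (MAGNUS_B + td2m) - MAGNUS_A * t2m / (MAGNUS_B + t2m))
  pmin(rh, 100)
}
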