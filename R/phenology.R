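#' @keywords internal
"_PACKAGE"

# Spectral bands shared by the simulated sensor.
SCENE_BANDS <- c("Blue", "Green", "Red", "NIR", "SWIR1", "SWIR2")

# Map class codes: 1 corn, 5 soybean, 9 other crop, 255 non-crop, 0 unclassified.
CLASS_CORN <- 1L
CLASS_SOY <- 5L
CLASS_OTHER <- 9L
CLASS_NONCROP <- 255L
CLASS_UNCLASSIFIED <- 0L
CROP_CODES <- c(CLASS_CORN, CLASS_SOY, CLASS_OTHER)

#' Phenology parameters for one crop class
#'
#' Describes a class's seasonal reflectance trajectory: a smooth unimodal
#' greenness "bump" centred at `peak_day` with width `season_width`, riding on
#' per-band off-season baselines. The NIR amplitude is derived from
#' `peak_gcvi` so that the noiseless GCVI (NIR/Green - 1) at the seasonal peak
#' equals `peak_gcvi` exactly.
#'
#' @param class_id crop class code (1 corn, 5 soybean, 9 other).
#' @param peak_day fraction of year in [0, 1) at maximum greenness.
#' @param peak_gcvi unitless GCVI maximum (> 0).
#' @param season_width std-dev-like width of the seasonal bump, fraction of
#'   year (> 0).
#' @param base_reflectance named per-band off-season reflectance, each in
#'   (0, 1).
#' @param amplitude named per-band seasonal swing; the NIR entry is ignored
#'   and recomputed from `peak_gcvi`.
#' @param noise_sd additive Gaussian observation noise std dev per band.
#' @return an object of class `phenology_params`.
#' @export
phenology_params <- function(class_id, peak_day, peak_gcvi, season_width,
                             base_reflectance, amplitude, noise_sd = 0.015) {
  stopifnot(
    peak_day >= 0, peak_day < 1,
    season_width > 0,
    peak_gcvi > 0,
    noise_sd >= 0,
    setequal(names(base_reflectance), SCENE_BANDS),
    setequal(names(amplitude), SCENE_BANDS),
    all(base_reflectance > 0), all(base_reflectance < 1)
  )
  base_reflectance <- base_reflectance[SCENE_BANDS]
  amplitude <- amplitude[SCENE_BANDS]
  peak_green <- base_reflectance[["Green"]] + amplitude[["Green"]]
  if (peak_green <= 0) stop("green reflectance at peak must stay positive")
  # peak NIR chosen so GCVI at the peak equals peak_gcvi
  amplitude[["NIR"]] <- (peak_gcvi + 1) * peak_green - base_reflectance[["NIR"]]
  structure(
    list(
      class_id = as.integer(class_id), peak_day = peak_day,
      peak_gcvi = peak_gcvi, season_width = season_width,
      base_reflectance = base_reflectance, amplitude = amplitude,
      noise_sd = noise_sd
    ),
    class = "phenology_params"
  )
}

#' Default per-class phenologies
#'
#' Encodes the ordering facts the simulator must honour: soybean peaks later
#' and higher in GCVI than corn, and the "other" class is an early-peaking,
#' lower-amplitude winter-cereal-like curve so all three classes are mutually
#' distinguishable.
#'
#' @param noise_sd observation noise std dev applied to every class.
#' @return named list of `phenology_params` for "corn", "soybean", "other".
#' @export
default_phenologies <- function(noise_sd = 0.015) {
  base <- c(Blue = 0.06, Green = 0.08, Red = 0.10, NIR = 0.18,
            SWIR1 = 0.25, SWIR2 = 0.20)
  amp <- c(Blue = -0.02, Green = -0.02, Red = -0.05, NIR = NA_real_,
           SWIR1 = -0.08, SWIR2 = -0.10)
  list(
    corn = phenology_params(CLASS_CORN, peak_day = 0.54, peak_gcvi = 5.0,
                            season_width = 0.085, base, amp, noise_sd),
    soybean = phenology_params(CLASS_SOY, peak_day = 0.60, peak_gcvi = 6.5,
                               season_width = 0.075, base, amp, noise_sd),
    other = phenology_params(CLASS_OTHER, peak_day = 0.42, peak_gcvi = 3.5,
                             season_width = 0.09, base, amp, noise_sd)
  )
}

# Smooth unimodal bump in [0, 1]: Gaussian in circular distance on the unit
# year, maximum 1 at peak_day.
season_bump <- function(t, peak_day, season_width) {
  d <- abs(t - peak_day)
  d <- pmin(d, 1 - d)
  exp(-0.5 * (d / season_width)^2)
}

#' Noiseless seasonal reflectance of one band at time t
#'
#' @param params a `phenology_params` object.
#' @param band one of Blue, Green, Red, NIR, SWIR1, SWIR2.
#' @param t fraction of year in [0, 1); vectorised.
#' @return reflectance values, base + amplitude * bump(t).
#' @export
phenology_curve <- function(params, band, t) {
  stopifnot(inherits(params, "phenology_params"), all(t >= 0), all(t < 1))
  if (!band %in% SCENE_BANDS) {
    stop(sprintf("unknown band '%s'; expected one of %s",
                 band, paste(SCENE_BANDS, collapse = ", ")))
  }
  params$base_reflectance[[band]] +
    params$amplitude[[band]] * season_bump(t, params$peak_day, params$season_width)
}
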