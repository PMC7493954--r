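#' Acquisition schedule for a simulated sensor
#'
#' Emulates Landsat-like revisit: nominal acquisitions every `revisit_days`,
#' each observation independently lost to cloud with probability `cloud_prob`,
#' plus optional blackout windows (fractional-year intervals) in which no
#' valid observation exists at any pixel.
#'
#' @param revisit_days nominal days between acquisitions (> 0).
#' @param cloud_prob per-observation probability of invalidity, in [0, 1).
#' @param blackout_windows list of length-2 numeric vectors, each a
#'   half-open [start, end) fractional-year interval within [0, 1).
#' @return an `acquisition_schedule` object with the acquisition times.
#' @export
acquisition_schedule <- function(revisit_days = 8, cloud_prob = 0.35,
                                 blackout_windows = list()) {
  stopifnot(revisit_days > 0, cloud_prob >= 0, cloud_prob < 1)
  for (w in blackout_windows) {
    stopifnot(length(w) == 2, w[1] >= 0, w[2] <= 1, w[1] < w[2])
  }
  doy <- seq(1, 365, by = revisit_days)
  structure(
    list(times = (doy - 0.5) / 365, revisit_days = revisit_days,
         cloud_prob = cloud_prob, blackout_windows = blackout_windows),
    class = "acquisition_schedule"
  )
}

#' Scene layout: raster size, class mixture, and region structure
#'
#' @param nrow,ncol raster size in pixels.
#' @param mixture named class proportions over corn/soybean/other/noncrop;
#'   must sum to 1.
#' @param n_regions number of synthetic counties (Voronoi cells).
#' @param n_states number of model-training regions the counties group into.
#' @param extent_km width and height of the scene in km.
#' @return a `scene_layout` object; `pixel_area` is in square metres.
#' @export
scene_layout <- function(nrow = 64, ncol = 64,
                         mixture = c(corn = 0.33, soybean = 0.28,
                                     other = 0.24, noncrop = 0.15),
                         n_regions = 8, n_states = 2, extent_km = 100) {
  stopifnot(nrow >= 1, ncol >= 1, n_regions >= 1, n_states >= 1,
            n_states <= n_regions, extent_km > 0,
            setequal(names(mixture), c("corn", "soybean", "other", "noncrop")),
            abs(sum(mixture) - 1) < 1e-8, all(mixture >= 0))
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         mixture = mixture[c("corn", "soybean", "other", "noncrop")],
         n_regions = as.integer(n_regions), n_states = as.integer(n_states),
         extent_km = extent_km,
         pixel_area = (extent_km * 1000 / nrow) * (extent_km * 1000 / ncol)),
    class = "scene_layout"
  )
}

# Draw a label raster (codes 1/5/9/255) from the layout mixture.
draw_labels <- function(layout, seed) {
  codes <- c(CLASS_CORN, CLASS_SOY, CLASS_OTHER, CLASS_NONCROP)
  with_substream(seed, "labels", {
    m <- matrix(sample(codes, layout$nrow * layout$ncol, replace = TRUE,
                       prob = layout$mixture),
                nrow = layout$nrow, ncol = layout$ncol)
    storage.mode(m) <- "integer"
    m
  })
}

# Advance a label raster one year under a crop transition matrix.
# Non-crop pixels stay non-crop (field boundaries are stable).
advance_labels <- function(labels, transition, seed, key = "labels/next") {
  stopifnot(identical(rownames(transition), colnames(transition)),
            all(abs(rowSums(transition) - 1) < 1e-8))
  codes <- as.integer(rownames(transition))
  out <- labels
  with_substream(seed, key, {
    for (code in codes) {
      idx <- which(labels == code)
      if (length(idx)) {
        out[idx] <- sample(codes, length(idx), replace = TRUE,
                           prob = transition[as.character(code), ])
      }
    }
  })
  out
}

#' Default year-to-year crop transition probabilities
#'
#' Encodes prevalent corn-soy rotation: most soybean fields flip to corn the
#' next year and vice versa, while "other" crops mostly persist.
#'
#' @return a 3x3 row-stochastic matrix over codes 1, 5, 9.
#' @export
default_transition <- function() {
  m <- matrix(c(0.25, 0.65, 0.10,
                0.70, 0.20, 0.10,
                0.15, 0.15, 0.70),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("1", "5", "9"), c("1", "5", "9")))
  m
}

# Render a scene stack from a label raster: sample each pixel's class curve
# at schedule times, add truncated Gaussian noise, draw validity flags.
render_scene <- function(labels, phenologies, schedule, seed) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  times <- schedule$times
  if (length(times) == 0) stop("empty acquisition schedule")
  npix <- length(labels)
  nt <- length(times)
  values <- array(0, dim = c(npix, nt, length(SCENE_BANDS)),
                  dimnames = list(NULL, NULL, SCENE_BANDS))
  class_of <- c(corn = CLASS_CORN, soybean = CLASS_SOY, other = CLASS_OTHER)
  with_substream(seed, "scene", {
    for (nm in names(phenologies)) {
      p <- phenologies[[nm]]
      idx <- which(labels == p$class_id)
      if (!length(idx)) next
      for (b in SCENE_BANDS) {
        curve <- phenology_curve(p, b, times)
        obs <- matrix(curve, nrow = length(idx), ncol = nt, byrow = TRUE)
        if (p$noise_sd > 0) {
          obs <- obs + matrix(stats::rnorm(length(idx) * nt, sd = p$noise_sd),
                              nrow = length(idx))
        }
        values[idx, , b] <- pmin(pmax(obs, 0), 2)
      }
    }
    # non-crop pixels: flat bare/developed spectrum with mild noise
    idx <- which(labels == CLASS_NONCROP)
    if (length(idx)) {
      flat <- c(Blue = 0.10, Green = 0.12, Red = 0.14, NIR = 0.20,
                SWIR1 = 0.22, SWIR2 = 0.18)
      for (b in SCENE_BANDS) {
        obs <- matrix(flat[[b]], nrow = length(idx), ncol = nt) +
          matrix(stats::rnorm(length(idx) * nt, sd = 0.02), nrow = length(idx))
        values[idx, , b] <- pmin(pmax(obs, 0), 2)
      }
    }
  })
  valid <- with_substream(seed, "validity", {
    matrix(stats::runif(npix * nt) >= schedule$cloud_prob,
           nrow = npix, ncol = nt)
  })
  for (w in schedule$blackout_windows) {
    valid[, times >= w[1] & times < w[2]] <- FALSE
  }
  structure(
    list(times = times, bands = SCENE_BANDS, values = values, valid = valid,
         nrow = nrow(labels), ncol = ncol(labels)),
    class = "scene_stack"
  )
}

# Voronoi partition of the raster into counties, grouped into states by
# the county centres' column position.
make_region_partition <- function(layout, seed) {
  centres <- with_substream(seed, "regions", {
    cbind(stats::runif(layout$n_regions, 0.5, layout$nrow + 0.5),
          stats::runif(layout$n_regions, 0.5, layout$ncol + 0.5))
  })
  rows <- matrix(seq_len(layout$nrow), layout$nrow, layout$ncol)
  cols <- matrix(seq_len(layout$ncol), layout$nrow, layout$ncol, byrow = TRUE)
  d2 <- sapply(seq_len(layout$n_regions), function(k) {
    (rows - centres[k, 1])^2 + (cols - centres[k, 2])^2
  })
  region_id <- matrix(max.col(-d2, ties.method = "first"),
                      nrow = layout$nrow, ncol = layout$ncol)
  # group counties into states by ranking their centre column
  state_of <- if (layout$n_states == 1L) {
    rep(1L, layout$n_regions)
  } else {
    as.integer(cut(rank(centres[, 2], ties.method = "first"),
                   breaks = layout$n_states, labels = FALSE))
  }
  structure(
    list(region_id = region_id, regions = seq_len(layout$n_regions),
         state_of_region = state_of, n_states = layout$n_states),
    class = "region_partition"
  )
}

#' Simulate one synthetic scene year
#'
#' Draws per-pixel crop labels from the layout mixture, samples each pixel's
#' phenology curve at the schedule's acquisition times with additive noise,
#' draws per-observation cloud validity, and partitions the raster into
#' synthetic counties. Fully reproducible from `seed`.
#'
#' @param phenologies named list of `phenology_params` (corn/soybean/other).
#' @param schedule an `acquisition_schedule`.
#' @param layout a `scene_layout`.
#' @param seed integer master seed.
#' @return list with elements `scene` (scene_stack), `labels` (integer
#'   matrix of codes), `partition` (region_partition).
#' @export
simulate_scene <- function(phenologies = default_phenologies(),
                           schedule = acquisition_schedule(),
                           layout = scene_layout(), seed = 1L) {
  labels <- draw_labels(layout, seed)
  list(scene = render_scene(labels, phenologies, schedule, seed),
       labels = labels,
       partition = make_region_partition(layout, seed))
}

#' Derive a boolean cropland mask from a label raster
#'
#' Crop classes map to TRUE, non-crop to FALSE; `flip_rate` of pixels are
#' toggled to emulate an out-of-date land-cover mask.
#'
#' @param labels integer label matrix (codes 1/5/9/255).
#' @param flip_rate probability in [0, 0.5) that a pixel's mask value flips.
#' @param seed integer seed.
#' @param key substream label (vary per mask year).
#' @return logical matrix, TRUE where cropland.
#' @export
make_cropland_mask <- function(labels, flip_rate = 0, seed = 1L, key = "mask") {
  stopifnot(flip_rate >= 0, flip_rate < 0.5)
  mask <- labels != CLASS_NONCROP
  if (flip_rate > 0) {
    flip <- with_substream(seed, key, {
      matrix(stats::runif(length(labels)) < flip_rate,
             nrow = nrow(labels), ncol = ncol(labels))
    })
    mask <- xor(mask, flip)
  }
  mask
}

# June 1 .. Aug 31 as fractions of year: the key crop growing window.
PEAK_QUARTER <- c(152, 243) / 365

# Median per-pixel count of valid observations within the peak growing window.
median_peak_valid <- function(scene) {
  in_peak <- scene$times >= PEAK_QUARTER[1] & scene$times <= PEAK_QUARTER[2]
  stats::median(rowSums(scene$valid[, in_peak, drop = FALSE]))
}

#' Stress scenarios mirroring documented failure modes
#'
#' Returns a modified pipeline configuration:
#' \describe{
#'   \item{midseason_blackout}{adds a July 1 - Sep 30 blackout window covering
#'     both corn and soybean peaks, emulating a season with no clear imagery
#'     at the vegetation peak (soybean's high GCVI peak goes unseen).}
#'   \item{delayed_planting}{shifts the corn peak day later, three quarters of
#'     the way toward soybean's, emulating a late-planting year in which corn
#'     phenology resembles soybean's.}
#'   \item{low_revisit}{drops to a 16-day revisit with cloud losses so the
#'     median valid count in the peak growing window falls to about 4,
#'     emulating a single-satellite year.}
#' }
#'
#' @param name one of "midseason_blackout", "delayed_planting", "low_revisit".
#' @param config a pipeline config list (see [pipeline_config()]).
#' @return the modified config, with `$scenario` set to `name`.
#' @export
stress_scenario <- function(name, config) {
  valid <- c("midseason_blackout", "delayed_planting", "low_revisit")
  if (!name %in% valid) {
    stop(sprintf("unknown scenario '%s'; valid scenarios: %s",
                 name, paste(valid, collapse = ", ")))
  }
  cfg <- config
  if (name == "midseason_blackout") {
    s <- cfg$schedule
    cfg$schedule <- acquisition_schedule(
      s$revisit_days, s$cloud_prob,
      c(s$blackout_windows, list(c(181, 273) / 365)))
  } else if (name == "delayed_planting") {
    corn <- cfg$phenologies$corn
    soy <- cfg$phenologies$soybean
    corn$peak_day <- corn$peak_day + 0.75 * (soy$peak_day - corn$peak_day)
    cfg$phenologies$corn <- corn
  } else if (name == "low_revisit") {
    cfg$schedule <- acquisition_schedule(revisit_days = 16, cloud_prob = 0.35,
                                         blackout_windows =
                                           cfg$schedule$blackout_windows)
  }
  cfg$scenario <- name
  cfg
}
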