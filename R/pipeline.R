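#' Pipeline configuration
#'
#' Bundles every tunable of the simulate - extract - sample - train -
#' predict - mask - validate workflow. Defaults reproduce the production
#' settings: second-order harmonic basis with omega = 1.5, 50 km sampling
#' grid with 250 points per cell, 80/20 train/test split of the training
#' years, 500-tree random forests, one model per state, last-available
#' cropland-mask year.
#'
#' @param layout a `scene_layout`.
#' @param phenologies named list of `phenology_params`.
#' @param schedule an `acquisition_schedule`.
#' @param basis a `harmonic_basis`.
#' @param years simulated calendar years (consecutive).
#' @param train_years years whose samples are split 80/20 into train/test.
#' @param test_years hindcast years: all their samples are test.
#' @param train_fraction fraction of train-year samples used for training.
#' @param cell_km sampling grid cell side (km).
#' @param points_per_cell uniform points drawn per grid cell.
#' @param n_trees random-forest size.
#' @param mask_years years for which a cropland mask exists.
#' @param mask_flip_rate per-pixel flip probability emulating stale masks.
#' @param transition year-to-year crop transition matrix.
#' @param area_unit unit for area tables ("m2", "ha", "acre").
#' @param seed master seed; every stochastic stage derives a named
#'   substream from it.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(layout = scene_layout(),
                            phenologies = default_phenologies(),
                            schedule = acquisition_schedule(),
                            basis = harmonic_basis(),
                            years = 2016:2018,
                            train_years = 2017:2018,
                            test_years = 2016L,
                            train_fraction = 0.8,
                            cell_km = 50,
                            points_per_cell = 250,
                            n_trees = 500L,
                            mask_years = c(2011L, 2013L, 2016L),
                            mask_flip_rate = 0.02,
                            transition = default_transition(),
                            area_unit = "ha",
                            seed = 1L) {
  cfg <- structure(
    list(layout = layout, phenologies = phenologies, schedule = schedule,
         basis = basis, years = as.integer(years),
         train_years = as.integer(train_years),
         test_years = as.integer(test_years),
         train_fraction = train_fraction, cell_km = cell_km,
         points_per_cell = as.integer(points_per_cell),
         n_trees = as.integer(n_trees), mask_years = as.integer(mask_years),
         mask_flip_rate = mask_flip_rate, transition = transition,
         area_unit = area_unit, seed = as.integer(seed), scenario = "base"),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Errors name the offending field and its constraint; nothing runs on an
#' invalid config.
#'
#' @param cfg a `pipeline_config` (or plain list with the same fields).
#' @return `cfg`, invisibly.
#' @export
validate_pipeline_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
  }
  if (!inherits(cfg$layout, "scene_layout")) fail("layout", "not a scene_layout")
  if (!inherits(cfg$schedule, "acquisition_schedule")) {
    fail("schedule", "not an acquisition_schedule")
  }
  if (!inherits(cfg$basis, "harmonic_basis")) fail("basis", "not a harmonic_basis")
  for (nm in c("corn", "soybean", "other")) {
    if (!inherits(cfg$phenologies[[nm]], "phenology_params")) {
      fail("phenologies", sprintf("missing phenology_params for '%s'", nm))
    }
  }
  if (cfg$n_trees < 1) fail("n_trees", "must be >= 1")
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    fail("train_fraction", "must lie in (0, 1)")
  }
  if (length(intersect(cfg$train_years, cfg$test_years))) {
    fail("train_years", "overlaps test_years")
  }
  if (!all(c(cfg$train_years, cfg$test_years) %in% cfg$years)) {
    fail("years", "train_years and test_years must be subsets of years")
  }
  if (cfg$cell_km <= 0) fail("cell_km", "must be > 0")
  if (cfg$points_per_cell < 1) fail("points_per_cell", "must be >= 1")
  if (cfg$mask_flip_rate < 0 || cfg$mask_flip_rate >= 0.5) {
    fail("mask_flip_rate", "must lie in [0, 0.5)")
  }
  if (!length(cfg$mask_years)) fail("mask_years", "must be non-empty")
  if (!cfg$area_unit %in% names(AREA_UNITS)) {
    fail("area_unit", sprintf("must be one of %s",
                              paste(names(AREA_UNITS), collapse = ", ")))
  }
  invisible(cfg)
}

#' Simulate the multi-year study: labels, scenes, partition, masks
#'
#' The first year's labels are drawn from the layout mixture; later years
#' evolve under the crop transition matrix with the non-crop footprint held
#' fixed. One scene stack is rendered per year; one cropland mask is built
#' per available mask year (with the configured flip rate emulating
#' staleness).
#'
#' @param config a `pipeline_config`.
#' @return list with `labels_by_year`, `scenes_by_year`, `partition`,
#'   `masks_by_year`.
#' @export
simulate_years <- function(config) {
  validate_pipeline_config(config)
  yrs <- as.character(config$years)
  labels_by_year <- list()
  labels <- draw_labels(config$layout, config$seed)
  labels_by_year[[yrs[1]]] <- labels
  for (i in seq_along(yrs)[-1]) {
    labels <- advance_labels(labels, config$transition, config$seed,
                             key = paste0("labels/", yrs[i]))
    labels_by_year[[yrs[i]]] <- labels
  }
  scenes_by_year <- lapply(stats::setNames(yrs, yrs), function(yr) {
    render_scene(labels_by_year[[yr]], config$phenologies, config$schedule,
                 derive_seed(config$seed, paste0("year/", yr)))
  })
  masks_by_year <- lapply(
    stats::setNames(config$mask_years, config$mask_years),
    function(my) {
      make_cropland_mask(labels_by_year[[yrs[1]]], config$mask_flip_rate,
                         config$seed, key = paste0("mask/", my))
    })
  list(labels_by_year = labels_by_year, scenes_by_year = scenes_by_year,
       partition = make_region_partition(config$layout, config$seed),
       masks_by_year = masks_by_year)
}

# Predict one year's full map using the per-state models.
predict_full_map <- function(models, partition, fx, dims) {
  out <- matrix(CLASS_UNCLASSIFIED, dims[1], dims[2])
  for (st in names(models)) {
    in_state <- partition$state_of_region[partition$region_id] ==
      as.integer(st)
    model <- models[[st]]
    idx <- which(in_state & !fx$insufficient)
    if (length(idx)) {
      out[idx] <- predict_codes(model, fx$features[idx, , drop = FALSE])
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Run the full mapping and validation pipeline
#'
#' Executes simulate - extract - sample - train - predict - mask - validate
#' under a single config and returns a machine-readable report. Re-running
#' with an identical config reproduces the report bit-for-bit
#' (see [report_json()]).
#'
#' @param config a `pipeline_config`, or the path to a YAML config file.
#' @param out_dir optional directory; when given, intermediate artifacts
#'   (labels, maps, sample set, report) are written there as plain text.
#' @param keep_state when TRUE the returned list carries the fitted models,
#'   features, and maps alongside the report (used by the stress analyses).
#' @return list with `report` and (optionally) `state`.
#' @export
run_pipeline <- function(config, out_dir = NULL, keep_state = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  yrs <- as.character(config$years)
  sim <- simulate_years(config)

  features_by_year <- lapply(sim$scenes_by_year, extract_features,
                             spec = config$basis)
  insufficiency <- vapply(features_by_year,
                          function(f) mean(f$insufficient), numeric(1))

  # stratified sampling and labelled records
  grid <- make_grid(config$layout$extent_km, config$layout$extent_km,
                    config$cell_km)
  pts <- sample_points(grid, config$points_per_cell,
                       seed = derive_seed(config$seed, "sampling"))
  sample <- attach_labels(pts, sim$labels_by_year, features_by_year,
                          config$layout, sim$partition)
  sample <- split_sample(sample, config$train_fraction, config$train_years,
                         config$test_years,
                         seed = derive_seed(config$seed, "split"))

  # one model per state
  states <- sort(unique(sim$partition$state_of_region))
  train <- sample[sample$split == "train", , drop = FALSE]
  models <- lapply(stats::setNames(as.character(states), states), function(st) {
    train_crop_classifier(train[train$state == as.integer(st), , drop = FALSE],
                          region = st, n_trees = config$n_trees,
                          seed = derive_seed(config$seed, paste0("rf/", st)),
                          spec = config$basis)
  })

  # held-out evaluation on test records
  test <- sample[sample$split == "test", , drop = FALSE]
  test$pred <- NA_integer_
  for (st in names(models)) {
    sel <- test$state == as.integer(st)
    if (any(sel)) {
      test$pred[sel] <- predict_sample(models[[st]], test[sel, , drop = FALSE])
    }
  }
  cm_heldout <- confusion(test$pred, test$label)
  heldout <- list(
    n_test = nrow(test),
    overall_accuracy = overall_accuracy(cm_heldout),
    by_class = lapply(stats::setNames(as.character(CROP_CODES), CROP_CODES),
                      function(cl) as.list(users_producers(cm_heldout, cl)))
  )

  # full maps, masked by the last available mask year
  dims <- c(config$layout$nrow, config$layout$ncol)
  maps_by_year <- lapply(stats::setNames(yrs, yrs), function(yr) {
    m <- predict_full_map(models, sim$partition, features_by_year[[yr]], dims)
    my <- mask_year_for(as.integer(yr), config$mask_years)
    apply_mask(m, sim$masks_by_year[[as.character(my)]])
  })
  map_accuracy <- vapply(yrs, function(yr) {
    overall_accuracy(confusion(maps_by_year[[yr]], sim$labels_by_year[[yr]]))
  }, numeric(1))

  # regional area agreement (predicted vs label-derived), pooled region-years
  class_names <- c("1" = "corn", "5" = "soybean", "9" = "other")
  areas <- do.call(rbind, lapply(yrs, function(yr) {
    do.call(rbind, lapply(CROP_CODES, function(cl) {
      data.frame(
        year = as.integer(yr), class = class_names[[as.character(cl)]],
        region = sim$partition$regions,
        predicted = unname(aggregate_area(maps_by_year[[yr]], sim$partition,
                                          cl, config$layout$pixel_area,
                                          config$area_unit)),
        reference = unname(aggregate_area(sim$labels_by_year[[yr]],
                                          sim$partition, cl,
                                          config$layout$pixel_area,
                                          config$area_unit))
      )
    }))
  }))
  area_r2 <- lapply(stats::setNames(unname(class_names), class_names),
                    function(cn) {
    sub <- areas[areas$class == cn, ]
    r_squared(sub$reference, sub$predicted)
  })

  # soybean-corn rotation fraction, predicted vs label-derived, pooled
  rotation <- do.call(rbind, lapply(seq_along(yrs)[-1], function(i) {
    rp <- rotation_fraction(maps_by_year[[yrs[i - 1]]], maps_by_year[[yrs[i]]],
                            sim$partition)
    rl <- rotation_fraction(sim$labels_by_year[[yrs[i - 1]]],
                            sim$labels_by_year[[yrs[i]]], sim$partition)
    data.frame(
      year = as.integer(yrs[i]),
      predicted = sum(rp$soy_to_corn) /
        (sum(rp$soy_to_corn) + sum(rp$corn_to_corn)),
      reference = sum(rl$soy_to_corn) /
        (sum(rl$soy_to_corn) + sum(rl$corn_to_corn))
    )
  }))

  # whole-scene area trend (slope of area on year) per class
  trend <- lapply(stats::setNames(unname(class_names), class_names),
                  function(cn) {
    sub <- stats::aggregate(cbind(predicted, reference) ~ year,
                            data = areas[areas$class == cn, ], FUN = sum)
    list(predicted = area_trend(sub$year, sub$predicted),
         reference = area_trend(sub$year, sub$reference))
  })

  report <- list(
    scenario = config$scenario,
    seed = config$seed,
    settings = list(
      raster = dims, years = config$years, train_years = config$train_years,
      test_years = config$test_years, n_trees = config$n_trees,
      basis = list(n = config$basis$n, omega = config$basis$omega),
      cell_km = config$cell_km, points_per_cell = config$points_per_cell,
      train_fraction = config$train_fraction, area_unit = config$area_unit
    ),
    sample = list(
      n_records = nrow(sample),
      n_train = sum(sample$split == "train"),
      n_test = sum(sample$split == "test"),
      dropped = as.list(attr(sample, "dropped")),
      class_counts = as.list(table(factor(sample$label, levels = CROP_CODES)))
    ),
    insufficiency = as.list(insufficiency),
    heldout = heldout,
    map_accuracy = as.list(map_accuracy),
    area_r2 = area_r2,
    rotation = rotation,
    trend = trend
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
    for (yr in yrs) {
      write_raster_csv(sim$labels_by_year[[yr]],
                       file.path(out_dir, sprintf("labels_%s.csv", yr)))
      write_raster_csv(maps_by_year[[yr]],
                       file.path(out_dir, sprintf("map_%s.csv", yr)))
    }
    write_raster_csv(sim$partition$region_id, file.path(out_dir, "regions.csv"))
    write_sample_csv(sample, file.path(out_dir, "sample.csv"))
    utils::write.csv(areas, file.path(out_dir, "areas.csv"), row.names = FALSE)
    report_json(report, file.path(out_dir, "report.json"))
  }

  out <- list(report = report)
  if (keep_state) {
    out$state <- list(config = config, sim = sim,
                      features_by_year = features_by_year, sample = sample,
                      models = models, maps_by_year = maps_by_year,
                      test = test, areas = areas)
  }
  out
}

#' Paired base-versus-stress comparison
#'
#' Runs (or reuses) the base pipeline, then applies one documented failure
#' mode and measures the paired effect at matched seeds:
#' \describe{
#'   \item{midseason_blackout}{the hindcast year's scene is re-rendered with
#'     a July-September acquisition blackout (same labels, same noise and
#'     cloud draws) and re-predicted with the base models; reported are the
#'     base and stressed counts of true-soybean pixels predicted corn.}
#'   \item{delayed_planting}{the hindcast year's scene is re-rendered with
#'     corn's peak shifted toward soybean's (prediction time only); reported
#'     are base and stressed counts of true-corn pixels predicted soybean.}
#'   \item{low_revisit}{the whole pipeline is re-run under the sparse
#'     schedule; reported are base and stressed held-out accuracies.}
#' }
#'
#' @param config the base `pipeline_config`.
#' @param name scenario name (see [stress_scenario()]).
#' @param base optional precomputed result of
#'   `run_pipeline(config, keep_state = TRUE)`.
#' @return list with `scenario`, `base`, `stress` metric lists.
#' @export
run_stress <- function(config, name, base = NULL) {
  cfg2 <- stress_scenario(name, config)  # validates the name
  if (is.null(base)) base <- run_pipeline(config, keep_state = TRUE)
  st <- base$state
  yr <- as.character(config$test_years[1])
  if (name == "low_revisit") {
    stressed <- run_pipeline(cfg2)
    return(list(
      scenario = name,
      base = list(heldout_accuracy = base$report$heldout$overall_accuracy),
      stress = list(heldout_accuracy = stressed$report$heldout$overall_accuracy)
    ))
  }
  labels <- st$sim$labels_by_year[[yr]]
  scene2 <- render_scene(labels, cfg2$phenologies, cfg2$schedule,
                         derive_seed(config$seed, paste0("year/", yr)))
  fx2 <- extract_features(scene2, config$basis)
  dims <- c(config$layout$nrow, config$layout$ncol)
  map2 <- predict_full_map(st$models, st$sim$partition, fx2, dims)
  my <- as.character(mask_year_for(as.integer(yr), config$mask_years))
  map2 <- apply_mask(map2, st$sim$masks_by_year[[my]])
  cm_base <- confusion(st$maps_by_year[[yr]], labels)
  cm_stress <- confusion(map2, labels)
  if (name == "midseason_blackout") {
    list(scenario = name,
         base = list(soy_predicted_corn = cm_base["5", "1"]),
         stress = list(soy_predicted_corn = cm_stress["5", "1"]))
  } else {
    list(scenario = name,
         base = list(corn_predicted_soy = cm_base["1", "5"]),
         stress = list(corn_predicted_soy = cm_stress["1", "5"]))
  }
}
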