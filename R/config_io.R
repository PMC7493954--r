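# YAML round-trip for pipeline configurations.

#' Write a pipeline configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path output file path.
#' @export
write_pipeline_config <- function(config, path) {
  validate_pipeline_config(config)
  phen <- lapply(config$phenologies, function(p) {
    list(class_id = p$class_id, peak_day = p$peak_day,
         peak_gcvi = p$peak_gcvi, season_width = p$season_width,
         base_reflectance = as.list(p$base_reflectance),
         amplitude = as.list(p$amplitude), noise_sd = p$noise_sd)
  })
  out <- list(
    layout = list(nrow = config$layout$nrow, ncol = config$layout$ncol,
                  mixture = as.list(config$layout$mixture),
                  n_regions = config$layout$n_regions,
                  n_states = config$layout$n_states,
                  extent_km = config$layout$extent_km),
    phenologies = phen,
    schedule = list(revisit_days = config$schedule$revisit_days,
                    cloud_prob = config$schedule$cloud_prob,
                    blackout_windows =
                      lapply(config$schedule$blackout_windows, as.numeric)),
    basis = list(n = config$basis$n, omega = config$basis$omega),
    years = config$years, train_years = config$train_years,
    test_years = config$test_years, train_fraction = config$train_fraction,
    cell_km = config$cell_km, points_per_cell = config$points_per_cell,
    n_trees = config$n_trees, mask_years = config$mask_years,
    mask_flip_rate = config$mask_flip_rate,
    transition = apply(config$transition, 1, as.list, simplify = FALSE),
    area_unit = config$area_unit, seed = config$seed,
    scenario = config$scenario
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file written by [write_pipeline_config()].
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  phen <- lapply(raw$phenologies, function(p) {
    phenology_params(p$class_id, p$peak_day, p$peak_gcvi, p$season_width,
                     unlist(p$base_reflectance), unlist(p$amplitude),
                     p$noise_sd)
  })
  trans <- do.call(rbind, lapply(raw$transition, unlist))
  rownames(trans) <- names(raw$transition)
  cfg <- pipeline_config(
    layout = scene_layout(raw$layout$nrow, raw$layout$ncol,
                          unlist(raw$layout$mixture), raw$layout$n_regions,
                          raw$layout$n_states, raw$layout$extent_km),
    phenologies = phen,
    schedule = acquisition_schedule(raw$schedule$revisit_days,
                                    raw$schedule$cloud_prob,
                                    raw$schedule$blackout_windows),
    basis = harmonic_basis(raw$basis$n, raw$basis$omega),
    years = raw$years, train_years = raw$train_years,
    test_years = raw$test_years, train_fraction = raw$train_fraction,
    cell_km = raw$cell_km, points_per_cell = raw$points_per_cell,
    n_trees = raw$n_trees, mask_years = raw$mask_years,
    mask_flip_rate = raw$mask_flip_rate, transition = trans,
    area_unit = raw$area_unit, seed = raw$seed
  )
  cfg$scenario <- raw$scenario %||% "base"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
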