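# Shared fixtures. The default-config pipeline run and its stress
# comparisons are expensive, so they are computed once per test session.

.cache <- new.env(parent = emptyenv())

default_cfg <- function(seed = 42L) pipeline_config(seed = seed)

# Full default run (64x64, 3 years), with state kept for stress reuse.
cached_default_run <- function() {
  if (is.null(.cache$run)) {
    .cache$run <- run_pipeline(default_cfg(), keep_state = TRUE)
  }
  .cache$run
}

cached_stress <- function(name) {
  key <- paste0("stress_", name)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- run_stress(default_cfg(), name, base = cached_default_run())
  }
  .cache[[key]]
}

# Small noiseless, cloud-free world for separability/exactness checks.
noiseless_phenologies <- function() default_phenologies(noise_sd = 0)

clear_schedule <- function(revisit_days = 8) {
  acquisition_schedule(revisit_days = revisit_days, cloud_prob = 0)
}

# Per-pixel GCVI series max over valid observations.
pixel_max_gcvi <- function(scene, i) {
  v <- scene$valid[i, ]
  max(gcvi(scene$values[i, v, "NIR"], scene$values[i, v, "Green"]))
}

# Toy confusion matrix from the 3-pixel hand enumeration
# ref = [1, 5, 9], pred = [1, 1, 9].
toy_cm <- function() confusion(c(1L, 1L, 9L), c(1L, 5L, 9L))
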