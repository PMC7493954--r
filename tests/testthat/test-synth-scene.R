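test_that("phenology curves are unimodal with their maximum at peak_day", {
  phen <- default_phenologies()
  tgrid <- seq(0, 0.999, length.out = 1000)
  for (p in phen) {
    # zero-amplitude curve is the baseline exactly
    p0 <- p
    p0$amplitude[] <- 0
    expect_identical(phenology_curve(p0, "NIR", p$peak_day),
                     p$base_reflectance[["NIR"]])
    # brute-force grid: no t beats the peak (NIR amplitude is positive)
    curve <- phenology_curve(p, "NIR", tgrid)
    expect_true(all(phenology_curve(p, "NIR", p$peak_day) >= curve))
  }
  expect_error(phenology_curve(phen$corn, "Thermal", 0.5), "Thermal")
})

test_that("default phenologies encode the corn/soy ordering facts", {
  phen <- default_phenologies()
  expect_gt(phen$soybean$peak_day, phen$corn$peak_day)
  expect_gt(phen$soybean$peak_gcvi, phen$corn$peak_gcvi)
  # grid argmax of the GCVI curve comes earlier for corn than soybean
  tgrid <- seq(0, 0.999, length.out = 1000)
  argmax_gcvi <- function(p) {
    g <- gcvi(phenology_curve(p, "NIR", tgrid), phenology_curve(p, "Green", tgrid))
    tgrid[which.max(g)]
  }
  expect_lt(argmax_gcvi(phen$corn), argmax_gcvi(phen$soybean))
  # noiseless GCVI at the peak equals the declared peak_gcvi
  for (p in phen) {
    expect_equal(gcvi(phenology_curve(p, "NIR", p$peak_day),
                      phenology_curve(p, "Green", p$peak_day)),
                 p$peak_gcvi, tolerance = 1e-12)
  }
})

test_that("simulate_scene honours validity, mixture, and blackout contracts", {
  layout <- scene_layout(nrow = 8, ncol = 8, n_regions = 2, n_states = 1)
  sim <- simulate_scene(schedule = clear_schedule(), layout = layout, seed = 3)
  expect_true(all(sim$scene$valid))
  expect_true(all(sim$scene$values[!is.na(sim$scene$values)] >= 0))
  expect_true(all(sim$scene$values <= 2))

  dark <- acquisition_schedule(blackout_windows = list(c(0, 1)))
  sim2 <- simulate_scene(schedule = dark, layout = layout, seed = 3)
  expect_false(any(sim2$scene$valid))

  pure <- scene_layout(nrow = 8, ncol = 8,
                       mixture = c(corn = 1, soybean = 0, other = 0,
                                   noncrop = 0),
                       n_regions = 2, n_states = 1)
  sim3 <- simulate_scene(layout = pure, seed = 3)
  expect_true(all(sim3$labels == 1L))

  empty <- clear_schedule()
  empty$times <- numeric(0)
  expect_error(phenomap:::render_scene(sim$labels, default_phenologies(),
                                       empty, 1),
               "empty")
})

test_that("identical seeds reproduce scenes bit-for-bit", {
  a <- simulate_scene(layout = scene_layout(nrow = 10, ncol = 10), seed = 11)
  b <- simulate_scene(layout = scene_layout(nrow = 10, ncol = 10), seed = 11)
  expect_identical(a$scene$values, b$scene$values)
  expect_identical(a$scene$valid, b$scene$valid)
  expect_identical(a$labels, b$labels)
  expect_identical(a$partition$region_id, b$partition$region_id)
  c <- simulate_scene(layout = scene_layout(nrow = 10, ncol = 10), seed = 12)
  expect_false(identical(a$labels, c$labels))
})

test_that("empirical class frequencies match the requested mixture", {
  mix <- c(corn = 0.33, soybean = 0.28, other = 0.24, noncrop = 0.15)
  layout <- scene_layout(nrow = 400, ncol = 250, mixture = mix)
  labels <- phenomap:::draw_labels(layout, seed = 5)
  n <- length(labels)
  for (cl in c(corn = 1L, soybean = 5L, other = 9L, noncrop = 255L)) {
    nm <- names(mix)[match(cl, c(1L, 5L, 9L, 255L))]
    p <- mix[[nm]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(labels == cl) - p), 3 * se)
  }
})

test_that("noiseless corn and soybean GCVI series are separable per pixel", {
  layout <- scene_layout(nrow = 16, ncol = 16,
                         mixture = c(corn = 0.5, soybean = 0.5, other = 0,
                                     noncrop = 0),
                         n_regions = 2, n_states = 1)
  sim <- simulate_scene(phenologies = noiseless_phenologies(),
                        schedule = clear_schedule(), layout = layout, seed = 9)
  corn_idx <- which(sim$labels == 1L)
  soy_idx <- which(sim$labels == 5L)
  corn_max <- vapply(corn_idx, function(i) pixel_max_gcvi(sim$scene, i),
                     numeric(1))
  soy_max <- vapply(soy_idx, function(i) pixel_max_gcvi(sim$scene, i),
                    numeric(1))
  expect_gt(min(soy_max), max(corn_max))
})

test_that("cropland masks flip at the requested rate", {
  layout <- scene_layout(nrow = 100, ncol = 100)
  labels <- phenomap:::draw_labels(layout, seed = 21)
  expect_identical(make_cropland_mask(labels, 0), labels != 255L)
  m <- make_cropland_mask(labels, 0.1, seed = 21)
  disagree <- mean(m != (labels != 255L))
  expect_gt(disagree, 0.08)
  expect_lt(disagree, 0.12)
  all_nc <- matrix(255L, 5, 5)
  expect_false(any(make_cropland_mask(all_nc, 0)))
  expect_error(make_cropland_mask(labels, 0.6))
})

test_that("stress scenarios modify the config as documented", {
  cfg <- default_cfg()
  expect_error(stress_scenario("solar_flare", cfg), "midseason_blackout")

  bl <- stress_scenario("midseason_blackout", cfg)
  w <- bl$schedule$blackout_windows[[length(bl$schedule$blackout_windows)]]
  for (p in cfg$phenologies[c("corn", "soybean")]) {
    expect_true(p$peak_day >= w[1] && p$peak_day < w[2])
  }

  dp <- stress_scenario("delayed_planting", cfg)
  gap0 <- abs(cfg$phenologies$corn$peak_day - cfg$phenologies$soybean$peak_day)
  gap1 <- abs(dp$phenologies$corn$peak_day - dp$phenologies$soybean$peak_day)
  expect_lt(gap1, gap0)

  lr <- stress_scenario("low_revisit", cfg)
  layout <- scene_layout(nrow = 10, ncol = 10)
  sim <- simulate_scene(schedule = lr$schedule, layout = layout, seed = 31)
  expect_lte(phenomap:::median_peak_valid(sim$scene), 4)
})

test_that("default schedule matches the documented clear-observation density", {
  # median clear observations per pixel in June-August is about 7
  sim <- simulate_scene(layout = scene_layout(nrow = 10, ncol = 10), seed = 13)
  med <- phenomap:::median_peak_valid(sim$scene)
  expect_gte(med, 6)
  expect_lte(med, 9)
})
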