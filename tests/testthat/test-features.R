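test_that("gcvi follows NIR/Green - 1 and invalidates non-positive green", {
  expect_equal(gcvi(0.4, 0.4), 0)
  expect_equal(gcvi(0.5, 0.25), 1.0)
  set.seed(1)
  nir <- runif(50, 0.1, 0.6)
  green <- runif(50, 0.02, 0.2)
  expect_equal(gcvi(nir, green), nir / green - 1, tolerance = 1e-15)
  expect_true(is.na(gcvi(0.5, 0)))
  expect_true(is.na(gcvi(0.5, -0.1)))
})

test_that("design matrix has the frozen [1, cos, sin, ...] column layout", {
  spec <- harmonic_basis()
  expect_identical(ncol(design_matrix(c(0.1, 0.2), spec)), 5L)
  expect_equal(design_matrix(0, spec)[1, ], c(c = 1, a1 = 1, b1 = 0,
                                              a2 = 1, b2 = 0))
  # element-wise trig oracle at arbitrary t and omega
  set.seed(2)
  t <- sort(runif(7))
  sp <- harmonic_basis(n = 3, omega = 2.25)
  X <- design_matrix(t, sp)
  for (i in seq_along(t)) {
    for (k in 1:3) {
      expect_equal(unname(X[i, 2 * k]), cos(2 * pi * k * 2.25 * t[i]))
      expect_equal(unname(X[i, 2 * k + 1]), sin(2 * pi * k * 2.25 * t[i]))
    }
  }
})

test_that("evaluate_harmonic matches term-by-term summation", {
  spec <- harmonic_basis()
  expect_equal(evaluate_harmonic(rep(0, 5), spec, c(0.1, 0.7)), c(0, 0))
  expect_equal(evaluate_harmonic(c(1, 0, 0, 0, 0), spec, c(0.1, 0.7)),
               c(1, 1))
  set.seed(3)
  beta <- rnorm(5)
  t <- runif(10)
  scalar <- vapply(t, function(ti) {
    s <- beta[1]
    for (k in 1:2) {
      s <- s + beta[2 * k] * cos(2 * pi * k * 1.5 * ti) +
        beta[2 * k + 1] * sin(2 * pi * k * 1.5 * ti)
    }
    s
  }, numeric(1))
  expect_equal(evaluate_harmonic(beta, spec, t), scalar, tolerance = 1e-12)
  expect_error(evaluate_harmonic(rep(0, 4), spec, 0.5), "5 coefficients")
})

test_that("fit_harmonic solves OLS and enforces the 5-point rule", {
  spec <- harmonic_basis()
  t6 <- seq(0.1, 0.9, length.out = 6)
  fit <- fit_harmonic(t6, rep(0.3, 6), spec)
  expect_equal(unname(fit), c(0.3, 0, 0, 0, 0), tolerance = 1e-10)

  # noiseless round trip through evaluate_harmonic
  set.seed(4)
  beta <- rnorm(5)
  t10 <- sort(runif(10))
  v <- evaluate_harmonic(beta, spec, t10)
  expect_equal(unname(fit_harmonic(t10, v, spec)), beta, tolerance = 1e-8)

  # fewer than 5 valid points -> insufficient sentinel
  expect_null(fit_harmonic(t10[1:4], v[1:4], spec))
  # rank-deficient design (one duplicated timestamp) -> sentinel, no crash
  expect_null(fit_harmonic(rep(0.5, 8), rnorm(8), spec))
})

test_that("fitted coefficients sit at a least-squares optimum", {
  spec <- harmonic_basis()
  set.seed(5)
  t <- sort(runif(12))
  v <- evaluate_harmonic(rnorm(5), spec, t) + rnorm(12, sd = 0.1)
  beta <- fit_harmonic(t, v, spec)
  rss <- function(b) sum((v - evaluate_harmonic(b, spec, t))^2)
  base <- rss(beta)
  for (j in 1:5) {
    for (d in c(-1e-3, 1e-3)) {
      b2 <- beta
      b2[j] <- b2[j] + d
      expect_gte(rss(b2), base)
    }
  }
})

test_that("exactly 2n+1 distinct timestamps interpolate the observations", {
  spec <- harmonic_basis()
  set.seed(6)
  t <- sort(runif(5))
  v <- rnorm(5)
  beta <- fit_harmonic(t, v, spec)
  expect_false(is.null(beta))
  expect_lt(max(abs(evaluate_harmonic(beta, spec, t) - v)), 1e-8)
})

test_that("fitting is invariant to observation order", {
  spec <- harmonic_basis()
  set.seed(7)
  t <- runif(9)
  v <- rnorm(9)
  perm <- sample(9)
  expect_equal(fit_harmonic(t, v, spec), fit_harmonic(t[perm], v[perm], spec),
               tolerance = 1e-12)
})

test_that("extract_features concatenates per-band fits in frozen order", {
  layout <- scene_layout(nrow = 4, ncol = 4, n_regions = 2, n_states = 1)
  sim <- simulate_scene(phenologies = noiseless_phenologies(),
                        schedule = clear_schedule(16), layout = layout,
                        seed = 8)
  fx <- extract_features(sim$scene)
  expect_identical(ncol(fx$features), 20L)
  expect_identical(colnames(fx$features), feature_names())
  expect_false(any(fx$insufficient))
  # per-band oracle equality for one pixel
  i <- 1L
  tv <- sim$scene$times[sim$scene$valid[i, ]]
  for (b in c("NIR", "SWIR1", "SWIR2")) {
    single <- fit_harmonic(tv, sim$scene$values[i, sim$scene$valid[i, ], b])
    expect_equal(unname(fx$features[i, paste0(b, "_", c("c", "a1", "b1", "a2",
                                                        "b2"))]),
                 unname(single), tolerance = 1e-10)
  }
  g <- gcvi(sim$scene$values[i, sim$scene$valid[i, ], "NIR"],
            sim$scene$values[i, sim$scene$valid[i, ], "Green"])
  expect_equal(unname(fx$features[i, 16:20]),
               unname(fit_harmonic(tv, g)), tolerance = 1e-10)
})

test_that("all-invalid pixels are flagged insufficient", {
  layout <- scene_layout(nrow = 3, ncol = 3, n_regions = 1, n_states = 1)
  sim <- simulate_scene(schedule = acquisition_schedule(
    blackout_windows = list(c(0, 1))), layout = layout, seed = 9)
  fx <- extract_features(sim$scene)
  expect_true(all(fx$insufficient))
  expect_true(all(is.na(fx$features)))
})

test_that("corrupted invalid observations never change the fit", {
  layout <- scene_layout(nrow = 5, ncol = 5, n_regions = 1, n_states = 1)
  sim <- simulate_scene(layout = layout, seed = 10)
  fx1 <- extract_features(sim$scene)
  scene2 <- sim$scene
  for (b in scene2$bands) {
    vals <- scene2$values[, , b]
    vals[!scene2$valid] <- 1.7  # nonsense but in-range
    scene2$values[, , b] <- vals
  }
  fx2 <- extract_features(scene2)
  expect_identical(fx1$features, fx2$features)
  expect_identical(fx1$insufficient, fx2$insufficient)
})

test_that("missing required bands are reported by name", {
  layout <- scene_layout(nrow = 2, ncol = 2, n_regions = 1, n_states = 1)
  sim <- simulate_scene(layout = layout, seed = 11)
  scene <- sim$scene
  scene$bands <- setdiff(scene$bands, "SWIR1")
  expect_error(extract_features(scene), "SWIR1")
})

test_that("the candidate feature registry matches the published catalogue", {
  reg <- feature_registry()
  expect_identical(registry_total(), 55L)
  expect_identical(registry_final_map_total(), 20L)
  spectral <- reg[reg$source == "Landsat", ]
  expect_true(all(spectral$n_features == 5L))
  expect_identical(spectral$group[spectral$in_final_map],
                   c("NIR", "SWIR1", "SWIR2", "GCVI"))
  weather <- reg[reg$source %in% c("gridMET", "TerraClimate"), ]
  expect_false(any(weather$in_final_map))
  expect_identical(sum(weather$n_features), 20L)
})
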