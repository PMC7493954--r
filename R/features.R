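#' Harmonic basis specification
#'
#' The per-pixel seasonal model is
#' \deqn{f(t) = c + \sum_{k=1}^{n} [a_k \cos(2\pi k\omega t) + b_k \sin(2\pi k\omega t)]}
#' with `t` the day of year as a fraction between 0 (January 1) and 1 (next
#' January 1). Defaults are a second-order series (n = 2) with omega = 1.5,
#' giving 2n + 1 = 5 features per band or vegetation index.
#'
#' @param n harmonic order (integer >= 1).
#' @param omega period control (unitless, > 0).
#' @return a `harmonic_basis` object.
#' @export
harmonic_basis <- function(n = 2L, omega = 1.5) {
  stopifnot(n >= 1, n == round(n), omega > 0)
  structure(list(n = as.integer(n), omega = omega), class = "harmonic_basis")
}

n_basis <- function(spec) 2L * spec$n + 1L

# Names for the coefficients of one series: c, a1, b1, a2, b2, ...
coef_names <- function(spec) {
  c("c", as.vector(rbind(paste0("a", seq_len(spec$n)),
                         paste0("b", seq_len(spec$n)))))
}

# Bands whose harmonic coefficients enter the final feature vector,
# in frozen band-major order.
FEATURE_BANDS <- c("NIR", "SWIR1", "SWIR2", "GCVI")

#' Green Chlorophyll Vegetation Index
#'
#' GCVI = NIR / Green - 1. Unlike NDVI it does not saturate at high leaf
#' area, which helps separate corn from soybean. Observations with
#' non-positive green reflectance yield `NA` (treated as invalid and excluded
#' from fitting) rather than an error.
#'
#' @param nir,green reflectance values (vectorised).
#' @return index values; `NA` where `green <= 0`.
#' @export
gcvi <- function(nir, green) {
  out <- nir / green - 1
  out[green <= 0] <- NA_real_
  out
}

#' Harmonic regression design matrix
#'
#' One row per timestamp; columns `[1, cos(2*pi*omega*t), sin(2*pi*omega*t),
#' cos(4*pi*omega*t), sin(4*pi*omega*t), ...]`, matching the frozen
#' coefficient ordering `[c, a1, b1, a2, b2, ...]`.
#'
#' @param t fractional-year timestamps.
#' @param spec a `harmonic_basis`.
#' @return numeric matrix, `length(t)` rows by `2n + 1` columns.
#' @export
design_matrix <- function(t, spec = harmonic_basis()) {
  stopifnot(length(t) >= 1)
  X <- matrix(1, nrow = length(t), ncol = n_basis(spec))
  for (k in seq_len(spec$n)) {
    ang <- 2 * pi * k * spec$omega * t
    X[, 2 * k] <- cos(ang)
    X[, 2 * k + 1] <- sin(ang)
  }
  colnames(X) <- coef_names(spec)
  X
}

#' Evaluate a fitted harmonic series at times t
#'
#' @param coefficients numeric vector of length `2n + 1`, ordered
#'   `[c, a1, b1, a2, b2, ...]`.
#' @param spec a `harmonic_basis`.
#' @param t fractional-year timestamps.
#' @return fitted values.
#' @export
evaluate_harmonic <- function(coefficients, spec = harmonic_basis(), t) {
  if (length(coefficients) != n_basis(spec)) {
    stop(sprintf("expected %d coefficients, got %d",
                 n_basis(spec), length(coefficients)))
  }
  drop(design_matrix(t, spec) %*% coefficients)
}

#' Fit a harmonic regression to one band's time series
#'
#' Ordinary (unweighted) least squares via QR decomposition. A series with
#' fewer than `2n + 1` finite observations, or whose design matrix is rank
#' deficient (e.g. duplicated timestamps only), returns `NULL` — the
#' "insufficient" sentinel — rather than an error, since at least 2n + 1 = 5
#' points are required to fit a second-order harmonic regression.
#'
#' @param t fractional-year timestamps of valid observations.
#' @param v observed values (same length as `t`); non-finite entries are
#'   dropped with their timestamps.
#' @param spec a `harmonic_basis`.
#' @return named coefficient vector `[c, a1, b1, ...]`, or `NULL` if
#'   insufficient.
#' @export
fit_harmonic <- function(t, v, spec = harmonic_basis()) {
  stopifnot(length(t) == length(v))
  keep <- is.finite(v) & is.finite(t)
  t <- t[keep]; v <- v[keep]
  p <- n_basis(spec)
  if (length(t) < p) return(NULL)
  qx <- qr(design_matrix(t, spec))
  if (qx$rank < p) return(NULL)
  beta <- qr.coef(qx, v)
  names(beta) <- coef_names(spec)
  beta
}

#' Extract the per-pixel harmonic feature raster from a scene stack
#'
#' Builds each pixel's GCVI series from valid observations, fits an
#' independent harmonic regression to NIR, SWIR1, SWIR2, and GCVI, and
#' concatenates coefficients band-major in the frozen order
#' `NIR, SWIR1, SWIR2, GCVI` x `[c, a1, b1, a2, b2]` — 20 features under the
#' default basis. A pixel is flagged insufficient if any of the four fits is
#' insufficient; such pixels later receive the unclassified code 0.
#'
#' @param stack a `scene_stack` containing at least Green, NIR, SWIR1, SWIR2.
#' @param spec a `harmonic_basis`.
#' @return list with `features` (n_pixels x 4(2n+1) matrix, NA rows where
#'   insufficient) and `insufficient` (logical vector).
#' @export
extract_features <- function(stack, spec = harmonic_basis()) {
  needed <- c("Green", "NIR", "SWIR1", "SWIR2")
  missing_b <- setdiff(needed, stack$bands)
  if (length(missing_b)) {
    stop(sprintf("scene stack is missing required band(s): %s",
                 paste(missing_b, collapse = ", ")))
  }
  npix <- dim(stack$values)[1]
  p <- n_basis(spec)
  feats <- matrix(NA_real_, nrow = npix, ncol = 4L * p,
                  dimnames = list(NULL, feature_names(spec)))
  insufficient <- logical(npix)
  times <- stack$times
  refl_bands <- c("NIR", "SWIR1", "SWIR2")
  for (i in seq_len(npix)) {
    vi <- stack$valid[i, ]
    if (sum(vi) < p) {
      insufficient[i] <- TRUE
      next
    }
    tv <- times[vi]
    # NIR/SWIR1/SWIR2 share the validity pattern: one QR, three RHS
    qx <- qr(design_matrix(tv, spec))
    if (qx$rank < p) {
      insufficient[i] <- TRUE
      next
    }
    beta3 <- qr.coef(qx, stack$values[i, vi, refl_bands])
    g <- gcvi(stack$values[i, vi, "NIR"], stack$values[i, vi, "Green"])
    beta_g <- fit_harmonic(tv, g, spec)
    if (anyNA(beta3) || is.null(beta_g)) {
      insufficient[i] <- TRUE
      next
    }
    feats[i, ] <- c(beta3[, "NIR"], beta3[, "SWIR1"], beta3[, "SWIR2"], beta_g)
  }
  feats[insufficient, ] <- NA_real_
  list(features = feats, insufficient = insufficient)
}

#' Names of the final-map feature vector entries
#'
#' @param spec a `harmonic_basis`.
#' @return character vector, e.g. `NIR_c, NIR_a1, ..., GCVI_b2`.
#' @export
feature_names <- function(spec = harmonic_basis()) {
  as.vector(t(outer(FEATURE_BANDS, coef_names(spec), paste, sep = "_")))
}
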