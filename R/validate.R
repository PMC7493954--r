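#' Confusion matrix between a predicted and a reference crop map
#'
#' Comparison is restricted to pixels where both maps hold a crop code in
#' {1, 5, 9}; pixels unclassified (0) or non-crop (255) in either map are
#' excluded symmetrically and their count reported.
#'
#' @param pred,ref integer code matrices with identical geometry.
#' @return 3x3 contingency matrix (rows = reference class, columns =
#'   predicted class) with an `"excluded"` attribute.
#' @export
confusion <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("map geometries differ")
  keep <- pred %in% CROP_CODES & ref %in% CROP_CODES
  cls <- as.character(CROP_CODES)
  cm <- table(factor(ref[keep], levels = CROP_CODES),
              factor(pred[keep], levels = CROP_CODES))
  cm <- matrix(as.numeric(cm), 3, 3, dimnames = list(ref = cls, pred = cls))
  attr(cm, "excluded") <- sum(!keep)
  cm
}

#' Overall accuracy of a confusion matrix
#'
#' The fraction of compared pixels with the same label in both maps:
#' trace / total.
#'
#' @param cm confusion matrix from [confusion()].
#' @return fraction in [0, 1]; `NA` when no pixels were compared.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) return(NA_real_)
  sum(diag(cm)) / total
}

#' User's and producer's accuracy for one crop class
#'
#' With TP/FP/FN the per-class true positives, false positives and false
#' negatives: user's accuracy = TP / (TP + FP) (precision) and producer's
#' accuracy = TP / (TP + FN) (recall). A zero denominator yields `NA`,
#' never 0.
#'
#' @param cm confusion matrix from [confusion()].
#' @param class crop class code (1, 5 or 9).
#' @return named numeric c(users, producers).
#' @export
users_producers <- function(cm, class) {
  key <- as.character(class)
  if (!key %in% rownames(cm)) {
    stop(sprintf("unknown class %s; expected one of %s",
                 key, paste(rownames(cm), collapse = ", ")))
  }
  tp <- cm[key, key]
  fp <- sum(cm[, key]) - tp
  fn <- sum(cm[key, ]) - tp
  c(users = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    producers = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

# m^2 per unit of area.
AREA_UNITS <- c(m2 = 1, ha = 10000, acre = 4046.8564224)

#' Aggregate per-region area of one class
#'
#' Pixel count of the class per region times the pixel area, converted to
#' the requested unit (1 acre = 4046.8564224 m^2).
#'
#' @param map integer code matrix.
#' @param partition a `region_partition` sharing the map geometry.
#' @param class class code to total.
#' @param pixel_area m^2 per pixel.
#' @param unit one of "m2", "ha", "acre".
#' @return named numeric vector of areas, one entry per region.
#' @export
aggregate_area <- function(map, partition, class, pixel_area,
                           unit = c("m2", "ha", "acre")) {
  unit <- match.arg(unit)
  if (!identical(dim(map), dim(partition$region_id))) {
    stop("map and partition geometries differ")
  }
  counts <- vapply(partition$regions, function(r) {
    sum(map == class & partition$region_id == r)
  }, numeric(1))
  stats::setNames(counts * pixel_area / AREA_UNITS[[unit]],
                  as.character(partition$regions))
}

#' Raw-value coefficient of determination
#'
#' R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2), computed on the values
#' themselves with no refitted regression, so it is bounded in (-Inf, 1] and
#' negative when predictions underperform the reference mean.
#'
#' @param y reference values (length >= 2, not all equal).
#' @param yhat predicted values.
#' @return R^2; `NA` when y is constant (zero denominator).
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  denom <- sum((y - mean(y))^2)
  if (denom == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / denom
}

#' Squared Pearson correlation
#'
#' Provided separately from the raw-value [r_squared()] to avoid confusion:
#' this is the r^2 used when comparing rotation fractions against survey
#' statistics.
#'
#' @param y,yhat numeric vectors.
#' @return squared correlation; `NA` when either vector is constant.
#' @export
r2_pearson <- function(y, yhat) {
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) return(NA_real_)
  stats::cor(y, yhat)^2
}

#' Soybean-corn rotation fraction per region
#'
#' Among pixels that are corn in the current year and were corn or soybean
#' the previous year, the fraction previously soybean:
#' soy-to-corn area / (soy-to-corn area + corn-to-corn area). Pixels with
#' any other prior class are excluded from numerator and denominator. A
#' region with a zero denominator is flagged undefined (`NA`).
#'
#' @param map_prev,map_curr integer code matrices for consecutive years.
#' @param partition a `region_partition`.
#' @return data.frame with columns `region, soy_to_corn, corn_to_corn,
#'   fraction` (pixel counts; multiply by pixel area for acreage).
#' @export
rotation_fraction <- function(map_prev, map_curr, partition) {
  if (!identical(dim(map_prev), dim(map_curr)) ||
      !identical(dim(map_curr), dim(partition$region_id))) {
    stop("map and partition geometries differ")
  }
  curr_corn <- map_curr == CLASS_CORN
  res <- lapply(partition$regions, function(r) {
    in_r <- partition$region_id == r
    s2c <- sum(in_r & curr_corn & map_prev == CLASS_SOY)
    c2c <- sum(in_r & curr_corn & map_prev == CLASS_CORN)
    data.frame(region = r, soy_to_corn = s2c, corn_to_corn = c2c,
               fraction = if (s2c + c2c > 0) s2c / (s2c + c2c) else NA_real_)
  })
  do.call(rbind, res)
}

#' Trend slope of planted area versus year
#'
#' Ordinary least-squares slope of area on calendar year, per region/class
#' series.
#'
#' @param years integer years (>= 2 distinct).
#' @param areas areas in any fixed unit.
#' @return slope (area units per year); `NA` with fewer than 2 distinct
#'   years.
#' @export
area_trend <- function(years, areas) {
  stopifnot(length(years) == length(areas))
  if (length(unique(years)) < 2) return(NA_real_)
  unname(stats::coef(stats::lm(areas ~ years))["years"])
}
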