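#' Train a random-forest crop classifier for one region
#'
#' Fits a 500-tree random forest (default hyperparameters otherwise) on the
#' 20 harmonic features and the three crop classes. A separate model is
#' trained for each region (the production analogue trains per state).
#' Deterministic given `seed`.
#'
#' @param sample training records (split == "train") for the region, from
#'   [split_sample()].
#' @param region region/state identifier stored in the model metadata.
#' @param n_trees number of trees; default 500.
#' @param seed integer seed.
#' @param spec the `harmonic_basis` that produced the features.
#' @return a `crop_classifier` object wrapping the forest plus metadata
#'   (region, n_trees, seed, feature ordering, class set).
#' @export
train_crop_classifier <- function(sample, region = NA, n_trees = 500L,
                                  seed = 1L, spec = harmonic_basis()) {
  fnames <- feature_names(spec)
  stopifnot(all(fnames %in% names(sample)), nrow(sample) >= 3)
  present <- sort(unique(sample$label))
  missing_cls <- setdiff(CROP_CODES, present)
  if (length(missing_cls)) {
    stop(sprintf("class(es) absent from training data: %s",
                 paste(missing_cls, collapse = ", ")))
  }
  x <- as.matrix(sample[, fnames, drop = FALSE])
  y <- factor(sample$label, levels = CROP_CODES)
  forest <- with_substream(seed, paste0("rf/", region), {
    randomForest::randomForest(x = x, y = y, ntree = n_trees)
  })
  structure(
    list(forest = forest, region = region, n_trees = as.integer(n_trees),
         seed = seed, feature_order = fnames, classes = CROP_CODES),
    class = "crop_classifier"
  )
}

# Deterministic class votes -> codes; ties go to the lowest class code.
predict_codes <- function(model, x) {
  votes <- stats::predict(model$forest, newdata = x, type = "vote",
                          norm.votes = FALSE)
  model$classes[max.col(votes, ties.method = "first")]
}

#' Predict held-out records with a trained classifier
#'
#' @param model a `crop_classifier`.
#' @param sample records carrying the model's feature columns.
#' @return integer vector of predicted class codes.
#' @export
predict_sample <- function(model, sample) {
  x <- as.matrix(sample[, model$feature_order, drop = FALSE])
  predict_codes(model, x)
}

#' Predict a full (pre-mask) crop map from a feature raster
#'
#' Per-pixel predicted code in {1, 5, 9}; pixels flagged insufficient (too
#' few valid observations to fit the harmonic regression) receive the
#' unclassified code 0. Prediction proceeds tile-by-tile with bounded
#' memory; tiling does not change results. No pixel receives 255 here —
#' cropland masking is a later stage.
#'
#' @param model a `crop_classifier`.
#' @param features n_pixels x 20 feature matrix from [extract_features()].
#' @param insufficient logical insufficiency flags, same pixel order.
#' @param dim integer c(nrow, ncol) of the output raster.
#' @param tile_size pixels per prediction tile.
#' @return integer matrix of codes {0, 1, 5, 9}.
#' @export
predict_map <- function(model, features, insufficient, dim,
                        tile_size = 4096L) {
  if (!identical(colnames(features), model$feature_order)) {
    stop("feature column ordering does not match the model's metadata")
  }
  npix <- nrow(features)
  stopifnot(prod(dim) == npix, length(insufficient) == npix)
  out <- rep(CLASS_UNCLASSIFIED, npix)
  ok <- which(!insufficient)
  for (start in seq_len(ceiling(length(ok) / tile_size)) * tile_size -
       tile_size + 1L) {
    idx <- ok[start:min(start + tile_size - 1L, length(ok))]
    out[idx] <- predict_codes(model, features[idx, , drop = FALSE])
  }
  matrix(as.integer(out), nrow = dim[1], ncol = dim[2])
}

#' Which mask year applies to a target map year
#'
#' Each year's map is masked by the last available cropland mask: the latest
#' mask year less than or equal to the target. Targets earlier than every
#' available mask use the earliest available mask (so e.g. with masks from
#' 2001 onward, 1999 and 2000 maps use the 2001 mask).
#'
#' @param target_year integer map year.
#' @param available_mask_years non-empty sorted integer vector.
#' @return the selected mask year.
#' @export
mask_year_for <- function(target_year, available_mask_years) {
  stopifnot(length(available_mask_years) >= 1)
  yrs <- sort(available_mask_years)
  eligible <- yrs[yrs <= target_year]
  if (!length(eligible)) yrs[1] else max(eligible)
}

#' Apply a cropland mask to a crop map
#'
#' Pixels where the mask is non-cropland become 255, overriding any
#' prediction; cropland pixels are unchanged. Idempotent.
#'
#' @param map integer code matrix.
#' @param mask logical matrix, TRUE where cropland.
#' @return masked code matrix.
#' @export
apply_mask <- function(map, mask) {
  if (!identical(dim(map), dim(mask))) {
    stop("map and mask geometries differ")
  }
  map[!mask] <- CLASS_NONCROP
  map
}
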