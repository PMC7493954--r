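#' Tile an extent with a square sampling grid
#'
#' Axis-aligned tiling with half-open cells `[x0, x1) x [y0, y1)`, so every
#' point of the extent falls in exactly one cell; boundary cells may be
#' partial. Used to draw a geographically stratified training sample (the
#' production analogue is a 50 km grid over the study states).
#'
#' @param width,height extent size (km).
#' @param cell_size grid cell side (km).
#' @return data.frame with columns `cell_id, x0, x1, y0, y1`.
#' @export
make_grid <- function(width, height, cell_size = 50) {
  stopifnot(width > 0, height > 0, cell_size > 0)
  nx <- ceiling(width / cell_size)
  ny <- ceiling(height / cell_size)
  cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  data.frame(
    cell_id = seq_len(nrow(cells)),
    x0 = (cells$ix - 1) * cell_size, x1 = pmin(cells$ix * cell_size, width),
    y0 = (cells$iy - 1) * cell_size, y1 = pmin(cells$iy * cell_size, height)
  )
}

#' Draw uniform points per grid cell, then filter to the study region
#'
#' @param grid a data.frame from [make_grid()].
#' @param per_cell number of uniform points per cell (>= 1).
#' @param region function(x, y) -> logical, TRUE inside the study region.
#' @param seed integer seed.
#' @return data.frame with columns `x, y, cell_id` (region-filtered).
#' @export
sample_points <- function(grid, per_cell, region = function(x, y) TRUE,
                          seed = 1L) {
  stopifnot(per_cell >= 1)
  pts <- with_substream(seed, "points", {
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      data.frame(
        x = stats::runif(per_cell, grid$x0[i], grid$x1[i]),
        y = stats::runif(per_cell, grid$y0[i], grid$y1[i]),
        cell_id = grid$cell_id[i]
      )
    }))
  })
  keep <- region(pts$x, pts$y)
  pts[keep, , drop = FALSE]
}

# Snap continuous scene coordinates (km, origin at the raster's top-left)
# to the nearest pixel; returns row/col, NA when out of bounds.
snap_to_pixel <- function(x, y, layout) {
  col <- floor(x / layout$extent_km * layout$ncol) + 1L
  row <- floor(y / layout$extent_km * layout$nrow) + 1L
  bad <- col < 1L | col > layout$ncol | row < 1L | row > layout$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = row, col = col)
}

#' Attach labels and features to sampled points
#'
#' Produces one record per (point, year) whose label is a crop class (corn 1,
#' soybean 5, other 9) and whose feature vector is non-insufficient; points
#' with a non-crop label, missing features, or coordinates outside the raster
#' are dropped (counts reported in the `"dropped"` attribute).
#'
#' @param points data.frame from [sample_points()].
#' @param labels_by_year named list (year -> integer label matrix).
#' @param features_by_year named list (year -> result of [extract_features()]).
#' @param layout the `scene_layout` the rasters share.
#' @param partition optional `region_partition`; adds `region` and `state`
#'   columns.
#' @return data.frame sample set: `x, y, year, label, cell_id` (+ `region`,
#'   `state`), and one column per feature.
#' @export
attach_labels <- function(points, labels_by_year, features_by_year, layout,
                          partition = NULL) {
  stopifnot(identical(sort(names(labels_by_year)),
                      sort(names(features_by_year))))
  px <- snap_to_pixel(points$x, points$y, layout)
  dropped <- c(out_of_bounds = 0L, non_crop = 0L, insufficient = 0L)
  recs <- list()
  for (yr in names(labels_by_year)) {
    labels <- labels_by_year[[yr]]
    fx <- features_by_year[[yr]]
    oob <- is.na(px$row)
    dropped[["out_of_bounds"]] <- dropped[["out_of_bounds"]] + sum(oob)
    idx <- cbind(px$row[!oob], px$col[!oob])
    lin <- idx[, 1] + (idx[, 2] - 1L) * nrow(labels)
    lab <- labels[lin]
    is_crop <- lab %in% CROP_CODES
    dropped[["non_crop"]] <- dropped[["non_crop"]] + sum(!is_crop)
    ok <- is_crop & !fx$insufficient[lin]
    dropped[["insufficient"]] <- dropped[["insufficient"]] +
      sum(is_crop & fx$insufficient[lin])
    if (!any(ok)) next
    sub <- points[!oob, , drop = FALSE][ok, , drop = FALSE]
    rec <- data.frame(x = sub$x, y = sub$y, year = as.integer(yr),
                      label = lab[ok], cell_id = sub$cell_id)
    if (!is.null(partition)) {
      rec$region <- partition$region_id[lin[ok]]
      rec$state <- partition$state_of_region[rec$region]
    }
    recs[[yr]] <- cbind(rec, fx$features[lin[ok], , drop = FALSE])
  }
  out <- if (length(recs)) do.call(rbind, recs) else {
    empty <- data.frame(x = numeric(), y = numeric(), year = integer(),
                        label = integer(), cell_id = integer())
    empty
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Tag a sample set with train/test splits
#'
#' Records from `train_years` are shuffled and split `train_fraction` /
#' `1 - train_fraction` (floor on the training count); all records from
#' `test_years` are tagged "test" (the hindcast evaluation set).
#'
#' @param sample data.frame from [attach_labels()].
#' @param train_fraction in (0, 1); default 0.8.
#' @param train_years,test_years disjoint integer year sets.
#' @param seed integer seed.
#' @return `sample` with an added `split` column in {"train", "test"}.
#' @export
split_sample <- function(sample, train_fraction = 0.8, train_years,
                         test_years = integer(), seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (length(intersect(train_years, test_years))) {
    stop("train_years and test_years overlap")
  }
  sample$split <- NA_character_
  sample$split[sample$year %in% test_years] <- "test"
  idx <- which(sample$year %in% train_years)
  n_train <- floor(length(idx) * train_fraction)
  shuffled <- with_substream(seed, "split", idx[sample.int(length(idx))])
  sample$split[utils::head(shuffled, n_train)] <- "train"
  sample$split[utils::tail(shuffled, length(idx) - n_train)] <- "test"
  sample[!is.na(sample$split), , drop = FALSE]
}
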