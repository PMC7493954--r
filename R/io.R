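# Plain-text artifact round-trips. Rasters are CSV matrices (one row per
# raster row, no header); sample sets are ordinary CSVs.

#' Write / read an integer or numeric raster as CSV
#' @param m matrix.
#' @param path file path.
#' @export
write_raster_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @param integer logical; read back as integer codes.
#' @export
read_raster_csv <- function(path, integer = TRUE) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  if (integer) storage.mode(m) <- "integer"
  m
}

#' Write / read a sample set as CSV
#' @param sample data.frame from [attach_labels()] / [split_sample()].
#' @param path file path.
#' @export
write_sample_csv <- function(sample, path) {
  utils::write.csv(sample, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_csv
#' @export
read_sample_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Serialize a pipeline run report to canonical JSON
#'
#' Full-precision, unboxed-scalar JSON so that identical runs produce
#' bit-identical report files.
#'
#' @param report list from [run_pipeline()].
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
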