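#' Candidate feature registry
#'
#' The static catalogue of the 55 features considered during feature
#' selection: harmonic coefficients of 7 spectral bands/vegetation indices
#' (5 each) plus 17 gridMET and 3 TerraClimate weather covariates. Only the
#' 20 harmonic coefficients of NIR, SWIR1, SWIR2 and GCVI enter the final
#' map; the weather covariates did not significantly improve classification
#' and are catalogued only — they are never computed by this package.
#'
#' @return a data.frame with columns `source`, `group`, `detail`,
#'   `n_features`, `in_final_map`.
#' @export
feature_registry <- function() {
  reg <- rbind(
    data.frame(source = "Landsat",
               group = c("Blue", "Green", "Red", "NIR", "SWIR1", "SWIR2",
                         "GCVI"),
               detail = "Harmonic coefficients",
               n_features = 5L,
               in_final_map = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)),
    data.frame(source = "gridMET",
               group = c("GDD", "Mean monthly VPD", "Mean monthly precip",
                         "Growing season precip", "Early season precip",
                         "Mean monthly max temp", "Mean monthly min temp",
                         "Aridity"),
               detail = c("Jan 1-Aug 31", "Jun, Jul", "Jun, Jul, Aug",
                          "May 1-Sep 15", "Jan 1-Apr 30",
                          "May, Jun, Jul, Aug", "May, Jun, Jul, Aug",
                          "Jun 1-Aug 31"),
               n_features = c(1L, 2L, 3L, 1L, 1L, 4L, 4L, 1L),
               in_final_map = FALSE),
    data.frame(source = "TerraClimate",
               group = c("Climate water deficit", "Soil moisture"),
               detail = c("May, Jul", "Aug"),
               n_features = c(2L, 1L),
               in_final_map = FALSE)
  )
  rownames(reg) <- NULL
  reg
}

#' Total number of candidate features in the registry
#' @return integer (55 under the default catalogue).
#' @export
registry_total <- function() sum(feature_registry()$n_features)

#' Number of features used in the final map
#' @return integer (20: 4 spectral groups x 5 harmonic coefficients).
#' @export
registry_final_map_total <- function() {
  reg <- feature_registry()
  sum(reg$n_features[reg$in_final_map])
}
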