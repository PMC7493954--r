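#!/usr/bin/env Rscript
# Stage 4 — map validation against the synthetic reference.
#
# From the stage-3 report and area table: raw-value R^2 between predicted
# and label-derived county areas, pooled soybean-corn rotation fractions,
# and the trend slope of planted area on year.

library(phenomap)

r <- jsonlite::read_json("results/run/report.json", simplifyVector = TRUE)
areas <- utils::read.csv("results/run/areas.csv")

cat("County-area raw-value R^2 (pooled region-years):\n")
for (cl in names(r$area_r2)) {
  cat(sprintf("  %s: %.4f\n", cl, r$area_r2[[cl]]))
}

cat("Soybean-corn rotation fraction (predicted vs label-derived):\n")
print(r$rotation, row.names = FALSE)

cat("Whole-scene area trend, ha/year (predicted | reference):\n")
for (cl in names(r$trend)) {
  cat(sprintf("  %s: %.1f | %.1f\n", cl,
              r$trend[[cl]]$predicted, r$trend[[cl]]$reference))
}

# per-county scatter table for downstream plotting
utils::write.csv(areas, "results/validation_areas.csv", row.names = FALSE)
cat("Per-county area table written to results/validation_areas.csv\n")
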