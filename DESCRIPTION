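Package: phenomap
Title: Harmonic-Regression Crop-Type Mapping on Simulated Multispectral Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates corn/soy/other multispectral scene time series with
    Landsat-like acquisition gaps, extracts per-pixel second-order harmonic
    regression features of NIR, SWIR1, SWIR2 and GCVI, trains per-region
    random-forest crop classifiers, applies cropland masking with a
    last-available-mask-year rule, and validates the resulting categorical
    maps with overall/user's/producer's accuracy, raw-value R-squared
    against regional area totals, soybean-corn rotation fractions, and
    area trend slopes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
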