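---
title: "Methods: harmonic-regression crop mapping on simulated scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonic-regression crop mapping on simulated scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomap)
```

## Overview

`phenomap` is a desk-scale, fully reproducible implementation of a
crop-type hindcast mapping pipeline: per-pixel harmonic regression on
cloud-gapped multispectral time series, grid-stratified training sampling,
per-state random-forest classification, cropland masking with a
last-available-mask-year rule, and a validation suite (map accuracies,
regional area R², rotation fractions, area trends). Because the real
inputs — decades of satellite imagery and official label products — are far
beyond desk scale, the pipeline is exercised on a synthetic scene simulator
whose statistical structure matches what the method assumes about the real
world. This vignette documents the model, the simulator and its defaults,
the numerical choices, and what the passing test suite does and does not
establish.

## The harmonic feature model

Every band or vegetation-index series at a pixel is treated as a periodic
function of the day of year $t \in [0, 1)$ and summarized by ordinary least
squares against the truncated Fourier basis

$$f(t) = c + \sum_{k=1}^{n}\left[a_k \cos(2\pi k \omega t) + b_k \sin(2\pi k \omega t)\right],$$

with order $n = 2$ and period control $\omega = 1.5$, giving $2n + 1 = 5$
coefficients per series. The classifier input concatenates the coefficients
of NIR, SWIR1, SWIR2, and GCVI $=$ NIR/Green $- 1$, band-major in the frozen
order $[c, a_1, b_1, a_2, b_2]$ — 20 features. The full candidate catalogue
(7 spectral groups plus 20 weather covariates, 55 entries) is kept as a
static registry, `feature_registry()`; the weather covariates never enter
the final map and are not computed here.

Numerical choices:

* **Solver.** QR-based least squares rather than normal equations, for
  robustness on nearly collinear designs. An independent normal-equations
  oracle in the test suite agrees to $10^{-6}$ on random series.
* **Insufficiency.** A series with fewer than 5 valid observations — or a
  rank-deficient design, e.g. all observations on one date — returns an
  explicit sentinel rather than a crash or a pseudo-inverse. Pixels with any
  insufficient band are left unclassified (code 0). Exactly-5-point fits are
  allowed; they interpolate the observations exactly, noise included, which
  is the documented behaviour of an "at least 5 points" rule.
* **GCVI validity.** An observation with Green $\le 0$ invalidates only that
  observation's GCVI value (dropped per-observation), not the pixel.
* **Order invariance.** Fits are invariant to observation order and to
  arbitrary corruption of invalid observations; both are property-tested.

## The scene simulator

The simulator provides what the pipeline assumes: per-class seasonal
reflectance curves sampled at irregular, cloud-thinned acquisition times.
Each class's curve is `base + amplitude × bump(t)` per band, where `bump` is
a Gaussian in circular distance on the unit year — smooth, unimodal, and
controlled by two interpretable parameters (peak day, season width). No
radiative-transfer or crop-growth realism is attempted; any unimodal curve
satisfying the ordering constraints below would do.

Defaults encode the facts the method relies on:

* **Corn** peaks at $t = 0.54$ (mid-July) with peak GCVI 5.0; **soybean**
  peaks later ($t = 0.60$) and higher (GCVI 6.5) — soybean is planted and
  harvested later than corn and usually shows the higher GCVI peak. The NIR
  amplitude is derived from the declared peak GCVI so the noiseless index at
  the peak is exact by construction. **Other** is an early-peaking
  ($t = 0.42$), lower-amplitude winter-cereal-like curve so the three-class
  problem is well posed.
* **Acquisitions** every 8 days (two satellites), each observation lost with
  probability 0.35 — yielding a median of about 7–8 clear observations per
  pixel in June–August, the documented availability in a good year.
* **Noise** is additive Gaussian per band (sd 0.015 reflectance units),
  truncated so reflectance stays in $[0, 2]$. Real sensor noise structure is
  not modelled.
* **Labels**: a 64×64 scene over a nominal 100 km extent, mixture
  corn 0.33 / soybean 0.28 / other 0.24 / non-crop 0.15 (crop shares close
  to the study region's sample distribution), evolving year to year under a
  rotation-heavy transition matrix (soy→corn 0.70, corn→soy 0.65,
  other persists 0.70) with the non-crop footprint fixed. Eight Voronoi
  counties grouped into two "states" support regional aggregation and
  per-state models.

Every stochastic artifact draws from its own RNG substream derived from the
master seed and a named key, so adding a draw never perturbs existing ones
and identical configs reproduce every raster bit for bit.

### Stress scenarios

Three documented failure mechanisms are first-class configurations:

* `midseason_blackout` adds a July 1 – September 30 acquisition blackout
  covering both crop peaks. With soybean's high GCVI peak unobserved, its
  fitted amplitude collapses toward corn's, and soy→corn confusions rise.
* `delayed_planting` shifts corn's peak day three quarters of the way toward
  soybean's, applied at prediction time only — a late-planting year seen by
  a model trained on normal years — inflating corn→soy confusions.
* `low_revisit` switches to a 16-day revisit (one satellite) with the same
  cloud losses, dropping the June–August median valid count to about 4, the
  documented worst-year availability; held-out accuracy must not improve.

## Sampling, training, masking

Training points are drawn 250 per 50 km grid cell (half-open cells, so every
point belongs to exactly one cell), snapped to the nearest pixel centre for
raster lookup. Records with a non-crop or missing label, or an insufficient
feature vector, are dropped with logged counts. Records from the training
years are split 80/20 (floor on the training count, deterministic shuffle);
the earliest simulated year contributes no training records and is evaluated
entirely as a hindcast. The split unit is the (point, year) record.

One 500-tree random forest (default hyperparameters otherwise) is trained
per state on the 20 features; ties among tree votes break to the lowest
class code, making prediction deterministic. Maps are predicted
tile-by-tile (tiling is verified not to change results), insufficient
pixels receive 0, and each year's map is masked to 255 by the last
available mask year (targets before the first mask use the earliest one).
Synthetic masks flip 2% of pixels to emulate staleness.

## Validation statistics

* **Confusion matrices** compare maps only where both hold a crop code
  {1, 5, 9}; 0/255 pixels are excluded symmetrically with a reported count.
  Overall accuracy is trace/total; user's and producer's accuracy are
  per-class precision and recall, with zero denominators flagged `NA`
  rather than reported as 0.
* **Area agreement** uses the raw-value
  $R^2 = 1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y)^2$ on county areas —
  no refitted regression, so it may be negative. The squared Pearson
  correlation is provided separately (`r2_pearson()`) and never conflated
  with it. Areas are pixel counts × pixel area, with m²/ha/acre conversion
  (1 acre = 4046.8564224 m²).
* **Rotation fraction** is soy→corn / (soy→corn + corn→corn) among current
  corn pixels; prior "other" pixels are excluded from both numerator and
  denominator, matching the survey formula; zero denominators are flagged.
* **Trend** is the OLS slope of planted area on calendar year.

## Problem sizes and what the tests show

The default study — a 64×64 scene, 3 years, 46 acquisition dates/year,
~2,500 sample records, two 500-tree forests — runs in well under a minute,
and is the size used by the test suite and the acceptance script; it is
large enough that binomial sampling checks (3 standard errors) and the
stress directionality counts are stable. On these clean, three-class scenes
the pipeline recovers held-out accuracy near 1 and county-area R² above
0.99. That demonstrates correctness of the machinery — feature extraction,
sampling, training, masking, and every statistic — under the conditions the
method assumes. It does not demonstrate real-world skill: real scenes have
within-class spectral diversity, mixed pixels, label noise, and
domain shift between training and hindcast decades, none of which the
simulator models (the stress scenarios probe the documented failure
directions, not their real magnitudes).

## Known limitations

* No geographic realism: no projections, adjacency-free Voronoi "counties",
  square pixels from a nominal extent.
* Within-class phenology is identical across pixels up to observation
  noise; class separability is therefore optimistic.
* Weather covariates are catalogued but never computed.
* Rasters are exchanged as plain-text CSV matrices with JSON/YAML sidecars;
  no geospatial raster formats are produced.
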