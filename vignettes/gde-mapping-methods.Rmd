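---
title: "Mapping groundwater-dependent ecosystems at desk scale: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping groundwater-dependent ecosystems at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdemapper)
```

## The inference problem

Groundwater-dependent ecosystems (GDEs) are the springs, riparian corridors
and phreatophyte stands of drylands: vegetation and surface water that stay
functional through the dry season because roots reach a shallow water table.
Direct evidence of groundwater use (isotopes, monitoring wells) does not
exist at landscape scale, so GDEs are *inferred* from how they look from
above. The working assumption is that a GDE pixel, relative to its xeric
surroundings, is

* **greener and wetter in the dry season** — elevated NIR reflectance,
  depressed SWIR1, hence high dry-season NDVI/NDMI/MSAVI and distinctive
  NDWI;
* **cooler than its neighbourhood** — evaporative cooling shows up as a
  negative land-surface-temperature (LST) spatial anomaly;
* **transpiring more water than the sky delivers** — the ratio of annual
  summed plant transpiration to annual summed precipitation (ETaP) exceeds
  1 only where roots tap storage that rain did not supply that year;
* **positioned plausibly** — over a water table within rooting depth
  (≤ 30 m) and in convergent topography (high compound topographic index,
  CTI).

`gdemapper` implements that inference as a complete, testable pipeline:
analysis-extent masking, engineering of the eleven predictors, a bagged
random-forest classifier with probability output and dynamic thresholding,
validation protocols, and the downstream storage-trend, protection and
zonal-overlap analyses. Because the global satellite archives behind the
real analysis cannot be bundled, the package includes a first-class
synthetic-scene generator whose outputs exercise every stage end to end.

## The synthetic scenes

`generate_scene()` builds a landscape in which the assumptions above are
*true by construction*, with one dial — `contrast` — controlling how
strongly:

* GDE patches are drawn as random-walk riparian corridors dilated to
  1–3 px, 1–2 px spring discs, and smoothed-noise phreatophyte blobs,
  mixed by `patch_geometry`, and trimmed so the truth mask hits the
  requested `gde_fraction` exactly.
* In dry-season observations, GDE pixels shift NIR up and SWIR1 down by
  `contrast * noise_sd` reflectance units, cool by `contrast * delta_t`
  °C (default 2 °C per unit), and carry an annual
  transpiration:precipitation ratio of `0.8 + 0.3 * contrast` against a
  matrix value of 0.8. Wet-season observations shrink these departures to
  a quarter, so compositing must actually select the dry window.
* Depth to groundwater is shallow (0.5–15 m) under every truth pixel and
  deep-tailed (up to `dtg_range[2]` = 100 m) in the matrix; cropland,
  built-up, open-water and humid-climate pockets are painted on non-GDE
  pixels so masking can never remove truth (the simulator contract tested
  in the suite).
* Each component (terrain, patches, land cover, reflectance, forcing,
  storage) draws from its own RNG stream derived from the master seed, so
  adding one never perturbs the others.

At `contrast = 0` GDE pixels are statistically identical to the matrix;
the suite verifies that every predictor's truth/matrix overlap index then
exceeds 0.95 (on samples large enough for the histogram estimator, which
converges to 1 from below and reads only ~0.93 on *identical*
distributions at n ≈ 1500).

The defaults — 200 × 200 pixels at 1 arcsecond, 3 years with 3 dry- and 3
wet-season observations each, `contrast = 2`, 5% cloud, 2% reflectance
noise — are the package's standing study conditions; the acceptance
surface is evaluated on them, never on re-tuned variants. What the scenes
do **not** emulate: radiative transfer, sensor geometry, correlated cloud
fields, terrain-coupled patch placement (patches are placed independently
of the DEM, so CTI carries no signal here), and real spatial covariance
structure. Passing tests therefore demonstrate that the *computations*
are correct and that the pipeline recovers a planted signal of plausible
shape — not that the real-world map is accurate.

## Extent masking

The analysis extent is the pixelwise conjunction of three binary masks:
dryland climate classes (`B`, `Csa`, `Csb`, `Csc`), a land-cover screen
removing cropland, built-up land and open water, and the shallow-water
condition `DTG ≤ 30 m` (inclusive bound; 30.01 m is out). Depth to
groundwater is gap-filled before thresholding: open-water pixels get
DTG = 0, a radius-1.5 focal mean in fill-only mode interpolates isolated
holes, and any pixel still missing is set to 0. The zero fill is applied
to *all* remaining holes — the conservative reading of the rule — with a
strict water-adjacent variant behind `strict_water_adjacent = TRUE`.
Radius 1.5 px selects exactly the 8-connected 3 × 3 neighbourhood, which
makes the operation reproducible without any particular platform.

## The eleven predictors

* **Dry-season compositing.** The dry window is 1 July–30 September at
  latitudes ≥ 0 and 1 January–31 March south of the equator, chosen per
  pixel by row latitude (latitude exactly 0 is treated as northern). Per
  year and pixel, the annual value is the mean of valid dry-window
  observations; the multi-year mean and the interannual coefficient of
  variation (CV = SD of annual values / |mean|) are the two metrics per
  index. The CV uses the sample (n−1) SD — the natural choice for 3–6
  annual values — with a `sd_type` switch; means within `1e-6` of zero
  give a nodata CV rather than an explosive ratio.
* **Quality screening.** Observations with scene cloud fraction strictly
  above 20% are dropped whole; retained scenes lose cloud/shadow/snow
  pixels; LST additionally loses pixels whose uncertainty is strictly
  above 5 °C. Both rules are strict exceedances, so values at exactly the
  bound are retained.
* **ETaP** averages *annual* ratios of summed transpiration to summed
  precipitation, not the ratio of pooled multi-year sums — the two differ
  under interannual variability (years at 0.5 and 1.5 average to 1.0).
  Zero-precipitation years drop out of a pixel's average.
* **CTI** is `ln(((acc + 1) · A_cell) / tan β)` with D8 single-direction
  flow accumulation (steepest descent of the eight neighbours,
  deterministic lowest-index tie-break), Horn's 3 × 3 slope, geodesic
  cell area in m², and `tan β` floored at 0.001 so flats stay finite.
  No algorithm is canonical for this layer, so it is validated by ordinal
  properties only (valley > ridge, contour-line symmetry).
* **LST spatial anomaly** subtracts, per observation, the mean LST of
  square windows of 9, 91 and 181 pixels (the 270 m / 2,700 m / 5,400 m
  neighbourhoods at 30 m resolution, even spans rounded up to odd so the
  focal pixel is centered), averages the three differences, then
  composites like the indices. Open water is excluded from every window
  mean and from the output. Summed-area tables make the large windows
  O(1) per pixel. Note one structural subtlety: for pixels deep inside a
  patch wider than a window, that window's mean contains the patch's own
  cooling and the scale contributes little signal — which is why the
  anomaly is multi-scale in the first place, and why, in the synthetic
  scenes, the spectral composites end up separating classes more sharply
  than the anomaly does.

`assemble_predictors()` enforces exactly the eleven canonical layers in a
fixed order; prediction refuses stacks whose layer order differs from the
training layout.

## Classifier, thresholding, validation

The classifier is a bagged ensemble of classification trees (Gini
impurity) with the tuned configuration: 40 trees, 5 candidate variables
per split, minimum leaf population 2, bag fraction 0.7 drawn with
replacement, and a 3,010-node cap per tree. The cap counts all nodes; the
ensemble backend controls growth by terminal nodes, so it maps to
⌈3,010 / 2⌉ = 1,505 leaves (further capped at the bag size, which the
backend requires). The probability layer is the fraction of trees voting
GDE — verified in the suite against per-tree traversal of the serialized
trees — and the out-of-bag error is recorded per model.

The "hard" map thresholds the probability layer. `dynamic_threshold()`
sweeps 0.00–1.00 in steps of 0.01 and returns the smallest threshold
maximizing accuracy on a validation set; `binarize()` codes GDE = 1,
non-GDE = 2, with probability exactly at the threshold mapping to GDE
(the stated 50% cut is inclusive). Validation reports use GDE as the
positive class; ratios with empty denominators are reported as missing
rather than zero.

Two protocols probe generalization. `regional_cv()` holds out one region
tag entirely; on scenes whose held-out region carries the same planted
signal, its accuracy tracks the pooled estimate, while a zero-contrast
holdout collapses recall with near-zero false positives — the
under-classification signature expected when a model meets ecosystems
that do not look like its training data. `overlap_index()` (shared-range
histograms with a pooled-sample Freedman–Diaconis bin width) quantifies
how well training-point predictor distributions cover the mapped domain;
it is calibrated in the suite against the closed form 2Φ(−1) ≈ 0.317 for
unit normals two SD apart.

## Post hoc analyses

* **Storage decomposition and trends.** GWS anomaly = TWS − soil
  moisture − SWE − canopy water, an exact linear identity. Trends are OLS
  slopes on decimal time over April 2002–April 2022; "declining" is
  sign-of-slope only, with the slope standard error reported for users
  who want to filter. A pure annual sinusoid contaminates the monthly-OLS
  slope by ~0.5% of its amplitude over 241 months (it is not exactly
  orthogonal to time on a finite monthly grid), which is far below the
  noise-driven uncertainty at the study's settings.
* **Area density and ratios.** Binary maps aggregate to coarse fractional
  cover with geodesic pixel areas (spherical-zone formula, authalic
  radius 6371.0072 km); trailing partial blocks are computed over their
  actual extent so 1-area is conserved exactly. The density denominator
  is total block area by default (`"valid"` available and flagged in
  metadata). Density must already be at the trend grid's resolution —
  the package refuses silent resampling. The declining-area,
  protection-status and threshold-overlap statistics are all
  area-weighted ratios with nodata cells excluded from numerator and
  denominator alike; protection categories partition GDE area exactly;
  the pastoral-style overlap uses strict exceedance of the cutoff.
* **Zonal summaries** use cell-center containment with the even-odd rule,
  so polygon holes need no special casing.

## Numerical and interface choices

* Grids are row-major, north-up, pixel-center coordinates, geographic
  WGS84 only; the nodata sentinel (−9999 by default) is compared exactly
  and `NA`s are converted on construction.
* Raster I/O uses the plain-text ESRI ASCII grid format written with 17
  significant digits, giving bit-exact round trips; points travel as CSV
  (`lon,lat,label,source,region`, labels validated against {GDE,
  NONGDE}), polygons as GeoJSON.
* The species consensus rule labels GDE at ≥ 2 phreatophyte flags,
  non-GDE at ≥ 3 not-phreatophyte flags, checked in that order; species
  meeting neither are excluded. The ordering of the two rules when both
  fire is a documented guess, not an assertion about any reference
  implementation.
* Hyperparameter search is exhaustive over a user-supplied grid with
  deterministic tie-breaks (fewer trees, then fewer variables per split).

## Problem sizes and what the tests show

The suite's end-to-end recovery runs ten replicate 200 × 200 scenes at
`contrast = 2` with 1,000 points per class and requires mean held-out
accuracy ≥ 0.90 and pixelwise truth agreement ≥ 0.85, plus a
`contrast = 0` control whose accuracy must sit at chance level
(0.55 ± 0.05 — slightly above 0.5 because the dynamic threshold is chosen
on the same held-out points it is scored on). Trend recovery uses 200
seeds of 241-month series; overlap calibration uses n = 10⁵. These sizes
were chosen so the statistics are stable at desk scale; they are the
package's reference conditions, not tuned values. Known limitations: no
real-geometry validation, no projected coordinate systems, no karst or
subterranean GDEs, and synthetic effect sizes that must not be read as
estimates of real GDE/matrix contrast.
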