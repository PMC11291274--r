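Package: gdemapper
Title: Desk-Scale Mapping of Groundwater-Dependent Ecosystems in Drylands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, desk-scale implementation of an inference-based pipeline for
    mapping groundwater-dependent ecosystems (GDEs) in dryland landscapes. Synthetic
    dryland scenes with cool, green, wet GDE "islands" over shallow water tables stand
    in for satellite data; the package builds the dryland analysis extent (climate,
    land-cover and depth-to-groundwater masking with gap-filling), engineers the eleven
    predictor variables (dry-season spectral index means and interannual coefficients
    of variation for NDVI, NDMI, NDWI and MSAVI; the transpiration-to-precipitation
    ratio ETaP; the compound topographic index; and a multi-scale land-surface-
    temperature spatial anomaly), trains a bagged random-forest classifier with
    probability output and dynamic thresholding, validates it with held-out and
    regional cross-validation splits and a distribution overlap index, and runs the
    downstream analyses: groundwater storage anomaly decomposition and trends,
    multi-resolution GDE area density, area-weighted zonal summaries, protection-status
    fractions and threshold-overlap statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
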