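# gdemapper

Desk-scale mapping of groundwater-dependent ecosystems (GDEs) in drylands.

Dryland springs, riparian corridors and phreatophyte stands survive the dry
season because their roots reach a shallow water table. With no global
groundwater-level network, their locations must be *inferred* from the land
surface: GDEs appear as blue/green islands that stay green and wet when
everything around them browns, run cooler than their neighbourhood, and
transpire more water annually than local precipitation supplies. `gdemapper`
implements that inference as a complete, tested R pipeline for scientists who
want to study, extend or audit the method without terabytes of satellite
imagery: synthetic dryland scenes with planted GDEs stand in for the real
archives, and every computational stage is real.

The pipeline:

1. **Analysis extent** — dryland climate classes (Köppen-style `B`/`Cs*`),
   minus agriculture/urban/open water, minus pixels with depth to groundwater
   above 30 m (after a three-step gap fill of the DTG layer).
2. **Eleven predictors** — dry-season mean and interannual CV of NDVI, NDMI,
   NDWI and MSAVI (with scene-level 20% cloud screening and per-pixel QA
   masking); ETaP, the mean annual ratio of summed plant transpiration to
   summed precipitation (ETaP > 1 flags a groundwater subsidy); the compound
   topographic index ln(((acc+1)·A)/tan β) from D8 flow accumulation; and a
   multi-scale LST spatial anomaly (focal pixel minus 9/91/181-pixel window
   means, averaged), with LST uncertainty screened at 5 °C.
3. **Classification** — a bagged random forest (40 trees, 5 variables per
   split, min leaf 2, bag fraction 0.7, 3,010-node cap) producing a per-pixel
   GDE probability (fraction of tree votes), thresholded dynamically to the
   accuracy-maximizing cut and coded GDE = 1 / non-GDE = 2.
4. **Validation** — stratified 80/20 held-out metrics (accuracy, precision,
   recall), regional cross-validation, and a histogram overlap index for
   comparing predictor distributions.
5. **Post hoc analyses** — groundwater storage anomaly decomposition
   (GWS = TWS − SM − SWE − canopy) and OLS trends over April 2002–April 2022;
   GDE area density at coarse resolutions via geodesic block aggregation; the
   area-weighted fraction of GDE area in declining-storage cells; protection
   status fractions; area-weighted zonal means over GeoJSON polygons; and
   threshold-overlap statistics (e.g. GDE area on >25% pastoral-use cells).

Rasters travel as plain-text ESRI ASCII grids with exact round trips, points
as CSV, polygons as GeoJSON.

## Worked example

```r
library(gdemapper)

cfg <- scenario_config(n_rows = 120, n_cols = 120, seed = 7)   # contrast 2 default
result <- run_gde_analysis(config = cfg, n_gde = 500, n_nongde = 500, n_barren = 100)

result$masks
#> <extent_masks> 4955 / 14400 pixels in extent (dtg_max = 30 m), 3.873 km2 analysed
result$model
#> <gde_rf_model> 40 trees, OOB error 0.000
#>   top importances: etap, ndmi_mean, ndvi_mean
result$report
#> <validation_report held-out 20%> acc 1.000, precision 1, recall 1 (tp 100 fp 0 fn 0 tn 120)
result$map
#> <gde_map> threshold 0.06: 1449 GDE / 3506 non-GDE / 9445 nodata pixels

result$truth_agreement            # 0.998 pixelwise agreement with the planted truth
result$gde_fraction_of_extent     # 0.292 of the analysed extent mapped as GDE

s  <- result$bundle$storage
tr <- ols_trend(gws_anomaly(s)$gws, s$dates)
tr$slope                          # -0.52 cm/yr recovered (planted -0.50)
```

Reading the output: about a third of the scene survives the climate /
land-cover / depth-to-groundwater masks (the `nodata` pixels of the map);
with the default planted contrast the forest separates GDE from matrix
points perfectly on the held-out 20% and reproduces the truth mask almost
pixel for pixel, and the mapped GDE share of the analysed extent (~29%)
sits near the planted fraction once masking is accounted for. The storage
trend analysis recovers the planted decline within its noise level. At
`contrast = 0` the same pipeline drops to chance accuracy — the recovery is
signal-driven, not an artefact.

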