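#' Dryland climate mask
#'
#' Marks pixels whose climate class is in the allowed dryland set: arid and
#' semi-arid (type `B`) plus the dry-summer temperate classes (`Csa`, `Csb`,
#' `Csc`) by default. Nodata propagates.
#'
#' @param climate_class a [categorical_grid()] over [climate_classes()].
#' @param allowed character vector of allowed class names.
#' @return Binary `raster_grid` (1 allowed, 0 not, nodata preserved).
#' @export
climate_mask <- function(climate_class, allowed = c("B", "Csa", "Csb", "Csc")) {
  lv <- attr(climate_class, "levels")
  if (is.null(lv)) lv <- climate_classes()
  bad <- setdiff(allowed, lv)
  if (length(bad))
    stop("unknown class code(s) in 'allowed': ", paste(bad, collapse = ", "))
  cls <- rg_classes(climate_class)
  out <- ifelse(is.na(cls), NA_real_, as.numeric(cls %in% allowed))
  rg_like(climate_class, out, "climate_ok")
}

#' Land-cover mask
#'
#' Excludes agricultural (`cropland`), urban (`built`) and open-water
#' (`water`, oceans and inland seas) pixels from the analysis extent.
#'
#' @param landcover a [categorical_grid()] over [landcover_classes()].
#' @return Binary `raster_grid` (1 retained, 0 masked, nodata preserved).
#' @export
landcover_mask <- function(landcover) {
  cls <- rg_classes(landcover)
  out <- ifelse(is.na(cls), NA_real_,
                as.numeric(!(cls %in% c("cropland", "built", "water"))))
  rg_like(landcover, out, "landcover_ok")
}

#' Gap-fill the depth-to-groundwater layer
#'
#' Three-step fill mirroring how open-water data gaps in a global DTG
#' product are handled: (1) DTG is set to 0 wherever `open_water` is 1
#' (water-table at the surface); (2) a 1.5-pixel focal mean in fill-only
#' mode interpolates isolated remaining nodata pixels from their valid
#' neighbours; (3) any pixel still nodata is assigned 0 (with
#' `strict_water_adjacent = TRUE`, step 3 zero-fills only pixels 8-adjacent
#' to water and leaves other holes nodata). Valid DTG values at non-water
#' pixels are never altered; the operation is idempotent.
#'
#' @param dtg depth-to-groundwater `raster_grid`, metres below surface.
#' @param open_water co-registered binary `raster_grid` (1 = open water).
#' @param strict_water_adjacent restrict the step-3 zero fill to
#'   water-adjacent pixels.
#' @return A gap-filled DTG `raster_grid`.
#' @export
fill_dtg <- function(dtg, open_water, strict_water_adjacent = FALSE) {
  .assert_registered(dtg, open_water, what = "dtg/open_water grids")
  v <- rg_values(dtg)
  w <- rg_values(open_water)
  v[!is.na(w) & w == 1] <- 0
  g <- rg_like(dtg, v, "dtg_filled")
  g <- focal_mean(g, 1.5, fill_only = TRUE)
  v <- rg_values(g)
  hole <- is.na(v)
  if (strict_water_adjacent && any(hole)) {
    wat <- !is.na(w) & w == 1
    near_water <- .box_mean(matrix(as.numeric(wat), nrow(v), ncol(v)), 1) > 0
    v[hole & near_water] <- 0
  } else {
    v[hole] <- 0
  }
  rg_like(dtg, v, "dtg_filled")
}

#' Build the model analysis extent
#'
#' Conjunction of the dryland climate mask, the land-cover mask and the
#' shallow-groundwater condition `dtg <= dtg_max` (30 m by default, the
#' rooting depth bound for phreatophytic vegetation; the bound is
#' inclusive). The analysed area is the geodesic area of extent pixels.
#'
#' @param climate_ok,landcover_ok binary `raster_grid`s from
#'   [climate_mask()] / [landcover_mask()].
#' @param dtg_filled gap-filled DTG `raster_grid` (metres).
#' @param dtg_max maximum depth to groundwater retained, metres.
#' @return An object of class `extent_masks`: the three component masks,
#'   the combined `extent` grid and `analysed_area_km2`.
#' @export
build_extent <- function(climate_ok, landcover_ok, dtg_filled, dtg_max = 30) {
  .assert_registered(climate_ok, landcover_ok, dtg_filled, what = "extent inputs")
  dv <- rg_values(dtg_filled)
  dtg_ok <- rg_like(dtg_filled, ifelse(is.na(dv), NA_real_,
                                       as.numeric(dv <= dtg_max)), "dtg_ok")
  c1 <- rg_values(climate_ok); c2 <- rg_values(landcover_ok); c3 <- rg_values(dtg_ok)
  ext <- ifelse(is.na(c1) | is.na(c2) | is.na(c3), NA_real_,
                as.numeric(c1 == 1 & c2 == 1 & c3 == 1))
  extent <- rg_like(climate_ok, ext, "extent")
  a <- cell_area_grid(extent)
  structure(list(climate_ok = climate_ok, landcover_ok = landcover_ok,
                 dtg_ok = dtg_ok, extent = extent, dtg_max = dtg_max,
                 analysed_area_km2 = sum(a[!is.na(ext) & ext == 1])),
            class = "extent_masks")
}

#' @export
print.extent_masks <- function(x, ...) {
  e <- rg_values(x$extent)
  cat(sprintf("<extent_masks> %d / %d pixels in extent (dtg_max = %g m), %.4g km2 analysed\n",
              sum(e == 1, na.rm = TRUE), length(e), x$dtg_max, x$analysed_area_km2))
  invisible(x)
}

# Extent of a synthetic scene bundle, built with the standard masking
# cascade (open water taken from the land-cover layer).
.bundle_extent <- function(bundle, dtg_max = 30) {
  lc <- rg_classes(bundle$landcover)
  water <- rg_like(bundle$landcover,
                   ifelse(is.na(lc), NA_real_, as.numeric(lc == "water")))
  build_extent(climate_mask(bundle$climate_class),
               landcover_mask(bundle$landcover),
               fill_dtg(bundle$dtg, water), dtg_max)
}
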