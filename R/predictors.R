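#' Canonical predictor layer names
#'
#' The eleven predictors, in canonical order: dry-season mean and
#' interannual coefficient of variation for NDVI, NDMI, NDWI and MSAVI,
#' the transpiration:precipitation ratio (ETaP), the compound topographic
#' index (CTI) and the multi-scale LST spatial anomaly.
#' @export
predictor_names <- function() {
  c("ndvi_mean", "ndvi_cv", "ndmi_mean", "ndmi_cv", "ndwi_mean", "ndwi_cv",
    "msavi_mean", "msavi_cv", "etap", "cti", "lst_anom")
}

#' Quality screening of scene observations
#'
#' Applies the observation-level and pixel-level quality rules: whole
#' observations with scene cloud fraction strictly greater than 20% are
#' dropped; in retained observations, reflectance bands are set to nodata
#' where the QA class is cloud, shadow or snow; land surface temperature is
#' set to nodata where its per-pixel uncertainty is strictly greater than
#' 5 degrees C (values at exactly the bounds are retained).
#'
#' @param observations list of `scene_observation`s.
#' @param max_cloud_fraction scene-level cloud screen (strict exceedance).
#' @param max_lst_uncert LST uncertainty screen, deg C (strict exceedance).
#' @return The screened observation list.
#' @export
qa_screen <- function(observations, max_cloud_fraction = 0.20,
                      max_lst_uncert = 5) {
  keep <- vapply(observations,
                 function(o) o$scene_cloud_fraction <= max_cloud_fraction,
                 TRUE)
  lapply(observations[keep], function(o) {
    qa <- rg_classes(o$qa)
    bad <- !is.na(qa) & qa %in% c("cloud", "shadow", "snow")
    for (b in c("red", "green", "nir", "swir1")) {
      v <- rg_values(o[[b]])
      v[bad] <- NA_real_
      o[[b]] <- rg_like(o[[b]], v)
    }
    unc <- rg_values(o$lst_uncert)
    lv <- rg_values(o$lst)
    lv[bad | is.na(unc) | unc > max_lst_uncert] <- NA_real_
    o$lst <- rg_like(o$lst, lv)
    o
  })
}

#' Spectral vegetation and water indices
#'
#' NDVI = (nir - red) / (nir + red); NDMI = (nir - swir1) / (nir + swir1);
#' NDWI = (green - nir) / (green + nir);
#' MSAVI = (2 nir + 1 - sqrt((2 nir + 1)^2 - 8 (nir - red))) / 2.
#' Zero denominators and negative radicands give nodata, as do nodata
#' inputs in any required band.
#'
#' @param obs a `scene_observation` (needs `red`, `green`, `nir`, `swir1`).
#' @param kind one of `"NDVI"`, `"NDMI"`, `"NDWI"`, `"MSAVI"`.
#' @return A `raster_grid` of the index.
#' @export
spectral_index <- function(obs, kind = c("NDVI", "NDMI", "NDWI", "MSAVI")) {
  kind <- match.arg(kind)
  nir <- rg_values(obs$nir)
  out <- switch(kind,
    NDVI = {
      red <- rg_values(obs$red)
      den <- nir + red
      ifelse(!is.na(den) & den != 0, (nir - red) / den, NA_real_)
    },
    NDMI = {
      swir1 <- rg_values(obs$swir1)
      den <- nir + swir1
      ifelse(!is.na(den) & den != 0, (nir - swir1) / den, NA_real_)
    },
    NDWI = {
      green <- rg_values(obs$green)
      den <- green + nir
      ifelse(!is.na(den) & den != 0, (green - nir) / den, NA_real_)
    },
    MSAVI = {
      red <- rg_values(obs$red)
      rad <- (2 * nir + 1)^2 - 8 * (nir - red)
      ifelse(!is.na(rad) & rad >= 0, (2 * nir + 1 - sqrt(rad)) / 2, NA_real_)
    })
  rg_like(obs$nir, out, tolower(kind))
}

# Month of each element of a Date vector.
.month_of <- function(d) as.integer(format(d, "%m"))
.year_of <- function(d) as.integer(format(d, "%Y"))

# Rows of a grid lying in the northern hemisphere (lat >= 0 is northern).
.north_rows <- function(grid) rg_lat_centers(grid) >= 0

# Per-year, per-pixel mean over dated grids restricted to the
# hemisphere-appropriate dry-season window (Jul-Sep north, Jan-Mar south).
# `items` is a list of list(date=, grid=). Returns a list of matrices, one
# per year (NA where a pixel has no valid observation that year).
.annual_dry_means <- function(items, years, template) {
  north <- .north_rows(template)
  months <- vapply(items, function(x) .month_of(x$date), 0L)
  yrs <- vapply(items, function(x) .year_of(x$date), 0L)
  lapply(years, function(y) {
    mean_over <- function(sel) {
      if (!any(sel)) {
        return(matrix(NA_real_, nrow(template$values), ncol(template$values)))
      }
      s <- 0; k <- 0
      for (it in items[sel]) {
        v <- rg_values(it$grid)
        ok <- !is.na(v)
        v[!ok] <- 0
        s <- s + v; k <- k + ok
      }
      ifelse(k > 0, s / k, NA_real_)
    }
    mN <- mean_over(yrs == y & months %in% 7:9)
    mS <- mean_over(yrs == y & months %in% 1:3)
    out <- mS
    out[north, ] <- mN[north, ]
    out
  })
}

# Pixelwise mean/SD/count across a list of matrices, NA-aware. Two-pass
# deviation sum keeps the SD numerically stable.
.stack_mean_sd <- function(mats, sd_type = "sample") {
  k <- Reduce(`+`, lapply(mats, function(a) !is.na(a)))
  s1 <- Reduce(`+`, lapply(mats, function(a) { a[is.na(a)] <- 0; a }))
  m <- ifelse(k > 0, s1 / k, NA_real_)
  m0 <- m; m0[is.na(m0)] <- 0
  dev2 <- Reduce(`+`, lapply(mats, function(a) {
    d <- (a - m0)^2; d[is.na(a)] <- 0; d
  }))
  denom <- if (sd_type == "sample") k - 1 else k
  s <- ifelse(denom > 0, sqrt(pmax(dev2, 0) / denom), NA_real_)
  list(mean = m, sd = s, n = k)
}

#' Dry-season mean and interannual coefficient of variation
#'
#' For each pixel, the annual value is the mean of valid observations in
#' that year's dry-season window, chosen per pixel by hemisphere
#' (1 July - 30 September at latitudes >= 0; 1 January - 31 March south of
#' the equator). The multi-year mean averages the annual values; the CV is
#' the standard deviation of the annual values divided by their mean
#' (sample, n-1, denominator by default). Pixels whose multi-year mean is
#' within `eps` of zero get a nodata CV; pixels with no valid dry-season
#' observation in any year are nodata throughout.
#'
#' @param index_obs list of dated grids: each element a list with `date`
#'   (a `Date`) and `grid` (a `raster_grid`).
#' @param years integer vector of years to composite.
#' @param sd_type `"sample"` (n-1) or `"population"` (n) standard deviation.
#' @param eps near-zero mean guard for the CV ratio.
#' @return List with `mean` and `cv` raster grids.
#' @export
dry_season_stats <- function(index_obs, years, sd_type = c("sample", "population"),
                             eps = 1e-6) {
  sd_type <- match.arg(sd_type)
  template <- index_obs[[1]]$grid
  ann <- .annual_dry_means(index_obs, years, template)
  st <- .stack_mean_sd(ann, sd_type)
  m <- st$mean
  cv <- ifelse(!is.na(m) & abs(m) >= eps & !is.na(st$sd), st$sd / abs(m),
               NA_real_)
  cv[st$n < 2] <- NA_real_
  list(mean = rg_like(template, m, "dry_season_mean"),
       cv = rg_like(template, cv, "dry_season_cv"))
}

#' Transpiration to precipitation ratio (ETaP)
#'
#' Per pixel, the mean over years of (annual summed transpiration /
#' annual summed precipitation). Values above 1 flag pixels where plant
#' water use exceeds infiltrated precipitation, the signature of a
#' groundwater subsidy. Years with zero annual precipitation at a pixel
#' are excluded from that pixel's average; if all years are excluded the
#' pixel is nodata.
#'
#' @param transp_monthly,precip_monthly named lists of monthly
#'   `raster_grid`s keyed `"YYYY-MM"`, in mm.
#' @param years years to average over (each must have complete monthly
#'   coverage in both inputs).
#' @return A `raster_grid` of the multi-year mean annual ratio.
#' @export
compute_etap <- function(transp_monthly, precip_monthly, years) {
  template <- transp_monthly[[1]]
  keys <- as.vector(outer(sprintf("%02d", 1:12), years,
                          function(m, y) sprintf("%d-%s", y, m)))
  missing_t <- setdiff(keys, names(transp_monthly))
  missing_p <- setdiff(keys, names(precip_monthly))
  if (length(missing_t) || length(missing_p))
    stop("mismatched calendars: missing month(s) ",
         paste(unique(c(missing_t, missing_p)), collapse = ", "))
  nr <- nrow(template$values); nc <- ncol(template$values)
  ssum <- matrix(0, nr, nc); scount <- matrix(0, nr, nc)
  for (y in years) {
    tsum <- matrix(0, nr, nc); psum <- matrix(0, nr, nc)
    ok <- matrix(TRUE, nr, nc)
    for (m in 1:12) {
      key <- sprintf("%d-%02d", y, m)
      tv <- rg_values(transp_monthly[[key]])
      pv <- rg_values(precip_monthly[[key]])
      ok <- ok & !is.na(tv) & !is.na(pv)
      tv[is.na(tv)] <- 0; pv[is.na(pv)] <- 0
      tsum <- tsum + tv; psum <- psum + pv
    }
    use <- ok & psum > 0
    ssum[use] <- ssum[use] + tsum[use] / psum[use]
    scount <- scount + use
  }
  etap <- ifelse(scount > 0, ssum / scount, NA_real_)
  rg_like(template, etap, "etap")
}

#' Compound topographic index (topographic wetness index)
#'
#' `cti = ln(((acc + 1) * A_cell) / tan(beta))` with `acc` the D8
#' single-flow-direction accumulation count (number of cells draining
#' through the pixel), `A_cell` the geodesic cell area in m^2 and `beta`
#' the slope from Horn's 3x3 operator; `tan(beta)` is floored at 0.001 so
#' flats stay finite. Flow goes to the steepest-descent neighbour of the
#' eight, distance-weighted; ties resolve deterministically to the lowest
#' neighbour index (N, NE, E, SE, S, SW, W, NW order). The index is high
#' in convergent valley positions and low on ridges.
#'
#' @param dem a `raster_grid` of elevations (m) with no nodata holes.
#' @return A `raster_grid` of CTI values.
#' @export
compute_cti <- function(dem) {
  z <- rg_values(dem)
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("dem must be at least 3x3")
  if (anyNA(z)) stop("dem must not contain nodata holes")
  lat <- rg_lat_centers(dem)
  R_m <- 6371007.2
  dy <- dem$cell_size * pi / 180 * R_m
  dx_row <- dy * pmax(cos(lat * pi / 180), 1e-6)

  # Horn slope on an edge-replicated pad
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sh <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  zNW <- sh(0, 0); zN <- sh(0, 1); zNE <- sh(0, 2)
  zW <- sh(1, 0);                  zE <- sh(1, 2)
  zSW <- sh(2, 0); zS <- sh(2, 1); zSE <- sh(2, 2)
  dx <- matrix(dx_row, nr, nc)
  p <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * dx)
  q <- ((zSW + 2 * zS + zSE) - (zNW + 2 * zN + zNE)) / (8 * dy)
  tanb <- pmax(sqrt(p^2 + q^2), 0.001)

  # D8 receivers: steepest descent among the 8 neighbours
  offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  recv <- matrix(0L, nr, nc)
  best <- matrix(0, nr, nc)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    zn <- .shift_matrix(z, -dr, -dc)   # neighbour value at each pixel
    dist <- sqrt((dr * dy)^2 + (dc * dx)^2)
    grad <- (z - zn) / dist
    better <- !is.na(grad) & grad > best
    best[better] <- grad[better]
    ri <- which(better)
    rr <- ((ri - 1) %% nr) + 1 + dr
    cc2 <- ((ri - 1) %/% nr) + 1 + dc
    recv[ri] <- rr + (cc2 - 1) * nr
  }

  acc <- rep(0, nr * nc)
  ordr <- order(z, decreasing = TRUE)
  for (i in ordr) {
    r <- recv[i]
    if (r > 0) acc[r] <- acc[r] + acc[i] + 1
  }
  area_m2 <- cell_area_grid(dem) * 1e6
  cti <- log(((matrix(acc, nr, nc) + 1) * area_m2) / tanb)
  rg_like(dem, cti, "cti")
}

#' Multi-scale LST spatial anomaly
#'
#' For each screened observation, the anomaly at a pixel is the mean over
#' the window scales of (pixel LST minus the mean LST over a square window
#' centered on the pixel, the focal pixel included, valid pixels only).
#' The default scales are odd windows of 9, 91 and 181 pixels, the
#' 270 m / 2,700 m / 5,400 m neighbourhoods at 30 m resolution. Open-water
#' pixels are excluded from every window mean and are nodata in the
#' output. Per-observation anomalies are composited exactly like the
#' spectral indices: annual dry-season means (hemisphere-appropriate
#' window) averaged over years.
#'
#' @param lst_obs list of dated grids (`list(date=, grid=)`) of screened
#'   LST, deg C.
#' @param water_mask co-registered binary `raster_grid` (1 = open water).
#' @param years years to composite.
#' @param scales_px odd window side lengths in pixels.
#' @return A `raster_grid` of the mean anomaly (deg C).
#' @export
compute_lst_anomaly <- function(lst_obs, water_mask, years,
                                scales_px = c(9, 91, 181)) {
  if (any(scales_px < 1)) stop("window smaller than 1 pixel")
  scales_px <- ifelse(scales_px %% 2 == 0, scales_px + 1, scales_px)
  template <- lst_obs[[1]]$grid
  .assert_registered(template, water_mask, what = "lst/water grids")
  wm <- rg_values(water_mask)
  water <- !is.na(wm) & wm == 1
  anom_items <- lapply(lst_obs, function(it) {
    v <- rg_values(it$grid)
    v[water] <- NA_real_
    a <- 0
    for (s in scales_px) a <- a + (v - .box_mean(v, (s - 1) / 2))
    list(date = it$date, grid = rg_like(template, a / length(scales_px)))
  })
  ann <- .annual_dry_means(anom_items, years, template)
  st <- .stack_mean_sd(ann)
  m <- st$mean
  m[st$n == 0 | water] <- NA_real_
  rg_like(template, m, "lst_anom")
}

#' Assemble the 11-layer predictor stack
#'
#' @param layers named list of exactly the eleven predictor grids (see
#'   [predictor_names()]); order-insensitive, duplicates and omissions are
#'   errors.
#' @return A `predictor_stack` with layers in canonical order.
#' @export
assemble_predictors <- function(layers) {
  want <- predictor_names()
  got <- names(layers)
  if (anyDuplicated(got))
    stop("duplicate layer(s): ", paste(unique(got[duplicated(got)]), collapse = ", "))
  missing <- setdiff(want, got); extra <- setdiff(got, want)
  if (length(missing) || length(extra))
    stop("predictor stack must hold exactly the 11 canonical layers; missing: {",
         paste(missing, collapse = ", "), "}; extra: {",
         paste(extra, collapse = ", "), "}")
  for (nm in want[-1]) .assert_registered(layers[[want[1]]], layers[[nm]],
                                          what = "predictor layers")
  structure(list(layers = layers[want]), class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("<predictor_stack> 11 layers, %d x %d px\n",
              nrow(g$values), ncol(g$values)))
  invisible(x)
}

#' Compute the full predictor stack for a synthetic scene
#'
#' Convenience wrapper running the whole feature-engineering stage on a
#' `scene_bundle`: QA screening, per-observation spectral indices,
#' dry-season mean/CV compositing for the four indices, ETaP, CTI and the
#' multi-scale LST anomaly (open water taken from the land-cover layer).
#'
#' @param bundle a `scene_bundle`.
#' @param scales_px LST anomaly window sides, pixels.
#' @return A `predictor_stack`.
#' @export
compute_predictor_stack <- function(bundle, scales_px = c(9, 91, 181)) {
  obs <- qa_screen(bundle$observations)
  years <- bundle$years
  layers <- list()
  for (kind in c("NDVI", "NDMI", "NDWI", "MSAVI")) {
    items <- lapply(obs, function(o)
      list(date = o$date, grid = spectral_index(o, kind)))
    st <- dry_season_stats(items, years)
    layers[[paste0(tolower(kind), "_mean")]] <- st$mean
    layers[[paste0(tolower(kind), "_cv")]] <- st$cv
  }
  layers$etap <- compute_etap(bundle$transp, bundle$precip, years)
  layers$cti <- compute_cti(bundle$dem)
  lc <- rg_classes(bundle$landcover)
  water <- rg_like(bundle$landcover,
                   ifelse(is.na(lc), NA_real_, as.numeric(lc == "water")))
  lst_items <- lapply(obs, function(o) list(date = o$date, grid = o$lst))
  layers$lst_anom <- compute_lst_anomaly(lst_items, water, years, scales_px)
  assemble_predictors(layers)
}
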