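#' Groundwater storage anomaly from the water-balance decomposition
#'
#' Groundwater storage anomaly = terrestrial water storage anomaly minus
#' the soil moisture, snow water equivalent and canopy water storage
#' anomalies, month by month (all in cm equivalent water thickness).
#'
#' @param series a `storage_series`.
#' @return Data frame with `date` and `gws`.
#' @export
gws_anomaly <- function(series) {
  stopifnot(inherits(series, "storage_series"))
  n <- length(series$dates)
  if (length(series$tws) != n || length(series$sm) != n ||
      length(series$swe) != n || length(series$canopy) != n)
    stop("misaligned dates: component series differ in length")
  data.frame(date = series$dates,
             gws = series$tws - series$sm - series$swe - series$canopy)
}

#' Ordinary-least-squares trend of a monthly series
#'
#' Slope of value on decimal time (years), restricted to the given date
#' window; missing months are simply absent from the fit. The reporting
#' window of interest for groundwater storage is April 2002 - April 2022.
#'
#' @param values numeric series.
#' @param dates `Date` vector aligned with `values`.
#' @param window length-2 `Date` vector (inclusive bounds); `NULL` uses
#'   all data.
#' @return List with `slope` (units/yr), `slope_se` and `n`.
#' @export
ols_trend <- function(values, dates,
                      window = as.Date(c("2002-04-01", "2022-04-30"))) {
  keep <- !is.na(values)
  if (!is.null(window)) keep <- keep & dates >= window[1] & dates <= window[2]
  if (sum(keep) < 24) stop("fewer than 24 in-window months")
  t_yr <- as.numeric(dates[keep] - dates[keep][1]) / 365.25
  fit <- stats::lm(values[keep] ~ t_yr)
  se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2]))
  list(slope = unname(stats::coef(fit)[2]), slope_se = se, n = sum(keep))
}

#' Per-cell groundwater trend grid
#'
#' Wraps a grid of OLS slopes (cm/yr) with its time window; nodata slope
#' pixels mark cells without usable data (for example glacier-masked
#' cells), and are excluded from every downstream ratio.
#'
#' @param slope a `raster_grid` of slopes, cm equivalent water thickness
#'   per year (nodata = invalid cell).
#' @param window length-2 `Date` vector describing the fitted period.
#' @export
trend_grid <- function(slope, window = as.Date(c("2002-04-01", "2022-04-30"))) {
  stopifnot(inherits(slope, "raster_grid"))
  structure(list(slope = slope, window = window), class = "trend_grid")
}

#' Fraction of GDE area in regions of declining groundwater storage
#'
#' Area-weighted share of mapped GDE area (density x geodesic cell area)
#' lying in trend cells with negative slope, among cells with trend data:
#' masked/nodata trend cells leave both numerator and denominator.
#' Invariant to uniform rescaling of the density layer.
#'
#' @param gde_density GDE area-density `raster_grid`, pre-aggregated to
#'   the trend grid's resolution.
#' @param trend a [trend_grid()] (or a slope `raster_grid`).
#' @return Proportion in \[0, 1\].
#' @export
fraction_declining <- function(gde_density, trend) {
  slope <- if (inherits(trend, "trend_grid")) trend$slope else trend
  .assert_registered(gde_density, slope, what = "density/trend grids")
  d <- rg_values(gde_density)
  s <- rg_values(slope)
  a <- cell_area_grid(gde_density)
  valid <- !is.na(d) & !is.na(s)
  den <- sum(d[valid] * a[valid])
  if (den == 0) stop("no GDE area among cells with trend data")
  sum(d[valid & s < 0] * a[valid & s < 0]) / den
}

#' Area-weighted zonal means over polygons
#'
#' Per zone, the geodesic-area-weighted mean of the value layer over the
#' cells whose centers fall inside the zone (even-odd rule, so holes and
#' multipolygon parts behave as in the GeoJSON standard). Zones covering
#' no valid cell get `NA`.
#'
#' @param value a `raster_grid`.
#' @param zones a `polygon_set` (see [read_polygons()]).
#' @return Data frame with `zone`, `mean`, `area_km2`, `n_cells`.
#' @export
zonal_area_weighted_mean <- function(value, zones) {
  v <- rg_values(value)
  a <- cell_area_grid(value)
  lon <- matrix(rg_lon_centers(value), nrow(v), ncol(v), byrow = TRUE)
  lat <- matrix(rg_lat_centers(value), nrow(v), ncol(v))
  res <- lapply(zones, function(z) {
    inside <- matrix(.points_in_rings(as.vector(lon), as.vector(lat), z$rings),
                     nrow(v), ncol(v))
    use <- inside & !is.na(v)
    data.frame(zone = z$name,
               mean = if (any(use)) sum(v[use] * a[use]) / sum(a[use]) else NA_real_,
               area_km2 = sum(a[use]),
               n_cells = sum(use), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Protection status of mapped GDE area
#'
#' Area-weighted fractions of GDE area (class 1 pixels) falling under a
#' protected area, a sustainable-groundwater-policy jurisdiction, both, or
#' neither. The four categories partition GDE area exactly;
#' `any = 1 - unprotected`.
#'
#' @param gde_binary `raster_grid` with the 1 = GDE / 2 = non-GDE coding
#'   (or a `gde_map`).
#' @param protected_area,policy_jurisdiction co-registered binary
#'   `raster_grid`s (nodata treated as 0 = outside).
#' @return Named list: `unprotected`, `protected_area_only`, `policy_only`,
#'   `both`, `any`, plus `gde_area_km2`.
#' @export
protection_fraction <- function(gde_binary, protected_area, policy_jurisdiction) {
  if (inherits(gde_binary, "gde_map")) gde_binary <- gde_binary$binary
  .assert_registered(gde_binary, protected_area, policy_jurisdiction,
                     what = "protection inputs")
  b <- rg_values(gde_binary)
  gde <- !is.na(b) & b == 1
  if (!any(gde)) stop("no GDE pixels in the map")
  a <- cell_area_grid(gde_binary)
  pav <- rg_values(protected_area); pov <- rg_values(policy_jurisdiction)
  pa <- !is.na(pav) & pav == 1
  po <- !is.na(pov) & pov == 1
  tot <- sum(a[gde])
  f <- function(m) sum(a[gde & m]) / tot
  out <- list(unprotected = f(!pa & !po),
              protected_area_only = f(pa & !po),
              policy_only = f(!pa & po),
              both = f(pa & po))
  out$any <- 1 - out$unprotected
  out$gde_area_km2 <- tot
  out
}

#' Overlap of GDE area with a thresholded covariate
#'
#' Area-weighted share of GDE area (density x cell area) on cells where a
#' covariate density strictly exceeds the cutoff (for example, more than
#' 25% pastoral land use), among cells where the covariate has data.
#'
#' @param gde_density GDE area-density `raster_grid`.
#' @param covariate_density co-registered covariate density `raster_grid`
#'   (nodata cells drop from numerator and denominator).
#' @param cutoff strict exceedance threshold.
#' @return Proportion in \[0, 1\].
#' @export
threshold_overlap <- function(gde_density, covariate_density, cutoff = 0.25) {
  .assert_registered(gde_density, covariate_density, what = "density grids")
  d <- rg_values(gde_density)
  cvr <- rg_values(covariate_density)
  a <- cell_area_grid(gde_density)
  valid <- !is.na(d) & !is.na(cvr)
  den <- sum(d[valid] * a[valid])
  if (den == 0) stop("no GDE area among cells with covariate data")
  sum(d[valid & cvr > cutoff] * a[valid & cvr > cutoff]) / den
}
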