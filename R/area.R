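#' Geodesic pixel area
#'
#' Area in km^2 of a spherical quadrangle of width `cell_size` degrees of
#' longitude and height `cell_size` degrees of latitude centered at
#' `lat_center`: `R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))` on the
#' authalic sphere (R = 6371.0072 km). Latitude bounds are clamped to +/-90
#' so polar cells get their true (reduced) area.
#'
#' @param lat_center latitude of the cell center, degrees (vectorized).
#' @param cell_size cell size in degrees.
#' @return Cell area(s) in km^2.
#' @examples
#' cell_area_km2(0, 1 / 120)   # ~0.859 km^2 for a 30-arcsecond cell
#' @export
cell_area_km2 <- function(lat_center, cell_size) {
  R <- 6371.0072
  phi_t <- pmin(lat_center + cell_size / 2, 90) * pi / 180
  phi_b <- pmax(lat_center - cell_size / 2, -90) * pi / 180
  R^2 * (cell_size * pi / 180) * (sin(phi_t) - sin(phi_b))
}

#' Per-pixel geodesic areas of a grid
#'
#' @param grid a [raster_grid()].
#' @return Numeric matrix of pixel areas (km^2); constant along rows.
#' @export
cell_area_grid <- function(grid) {
  a <- cell_area_km2(rg_lat_centers(grid), grid$cell_size)
  matrix(a, nrow(grid$values), ncol(grid$values))
}

#' Block aggregation of a binary grid to fractional cover
#'
#' Aggregates a {0,1} grid by `block x block` pixel blocks into the
#' area-weighted fraction of 1-pixels per block, using geodesic pixel areas.
#' This is the operation that turns a fine binary classification into a
#' coarse "area density" layer. Trailing partial blocks are computed over
#' their actual extent (no padding), so total 1-area is conserved exactly.
#'
#' @param binary a [raster_grid()] containing only 0, 1 and nodata.
#' @param block positive integer block edge, in pixels.
#' @param denominator `"total"` (default) divides by the full block area,
#'   nodata pixels included, matching a total-cell-area reading of density;
#'   `"valid"` divides by the area of valid pixels only. The choice is
#'   recorded in the output's `denominator` attribute.
#' @return A `raster_grid` of fractions in \[0, 1\]; blocks that are entirely
#'   nodata are nodata.
#' @export
aggregate_fraction <- function(binary, block, denominator = c("total", "valid")) {
  denominator <- match.arg(denominator)
  if (!is.numeric(block) || length(block) != 1 || block < 1 || block != round(block))
    stop("block must be a positive integer")
  v <- rg_values(binary)
  if (!all(v[!is.na(v)] %in% c(0, 1)))
    stop("invalid input: grid must contain only 0, 1 and nodata")
  a <- cell_area_grid(binary)
  nr <- nrow(v); nc <- ncol(v)
  nbr <- ceiling(nr / block); nbc <- ceiling(nc / block)
  out <- matrix(NA_real_, nbr, nbc)
  for (i in seq_len(nbr)) {
    rows <- ((i - 1) * block + 1):min(i * block, nr)
    for (j in seq_len(nbc)) {
      cols <- ((j - 1) * block + 1):min(j * block, nc)
      vb <- v[rows, cols, drop = FALSE]
      ab <- a[rows, cols, drop = FALSE]
      valid <- !is.na(vb)
      if (!any(valid)) next
      num <- sum(ab[valid & vb == 1])
      den <- if (denominator == "total") sum(ab) else sum(ab[valid])
      out[i, j] <- num / den
    }
  }
  g <- raster_grid(out, binary$origin_lon, binary$origin_lat,
                   binary$cell_size * block, binary$nodata,
                   paste0(binary$layer_name, "_density"))
  attr(g, "denominator") <- denominator
  g
}

# Denominator areas actually used by aggregate_fraction, block by block;
# lets callers verify area conservation and convert fractions back to km^2.
block_area_km2 <- function(binary, block, denominator = c("total", "valid")) {
  denominator <- match.arg(denominator)
  v <- rg_values(binary)
  a <- cell_area_grid(binary)
  nr <- nrow(v); nc <- ncol(v)
  nbr <- ceiling(nr / block); nbc <- ceiling(nc / block)
  out <- matrix(NA_real_, nbr, nbc)
  for (i in seq_len(nbr)) {
    rows <- ((i - 1) * block + 1):min(i * block, nr)
    for (j in seq_len(nbc)) {
      cols <- ((j - 1) * block + 1):min(j * block, nc)
      ab <- a[rows, cols, drop = FALSE]
      if (denominator == "valid") {
        valid <- !is.na(v[rows, cols, drop = FALSE])
        out[i, j] <- sum(ab[valid])
      } else out[i, j] <- sum(ab)
    }
  }
  out
}
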