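#' Rectangular georeferenced grid
#'
#' The universal gridded container of the pipeline: a north-up matrix of
#' values in a geographic (longitude/latitude, WGS84) coordinate system.
#' Row index increases southward from the north-west corner; pixels are
#' square in degrees and pixel coordinates refer to pixel centers.
#' Missing values are encoded by an explicit `nodata` sentinel (exact
#' equality), never by `NA`; `NA`s supplied at construction are converted
#' to the sentinel.
#'
#' @param values numeric matrix (rows = north to south).
#' @param origin_lon,origin_lat longitude/latitude of the north-west corner,
#'   in degrees.
#' @param cell_size pixel size in degrees (square pixels, > 0).
#' @param nodata sentinel value marking missing pixels.
#' @param layer_name short layer label.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:6, 2, 3), origin_lon = 10, origin_lat = 45,
#'                  cell_size = 1 / 120)
#' rg_lat_centers(g)
#' @export
raster_grid <- function(values, origin_lon = 0, origin_lat = 0,
                        cell_size = 1 / 3600, nodata = -9999,
                        layer_name = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive number")
  values[is.na(values)] <- nodata
  structure(
    list(values = values, origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat), cell_size = as.numeric(cell_size),
         nodata = as.numeric(nodata), layer_name = as.character(layer_name)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid '%s'> %d x %d @ %.8g deg, NW corner (%.6g, %.6g)\n",
              x$layer_name, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin_lon, x$origin_lat))
  v <- rg_values(x)
  cat(sprintf("  valid: %d / %d, range [%s, %s], nodata = %g\n",
              sum(!is.na(v)), length(v),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE))), x$nodata))
  invisible(x)
}

#' Grid values with nodata as NA
#'
#' @param grid a `raster_grid`.
#' @return Numeric matrix in which nodata pixels are `NA`.
#' @export
rg_values <- function(grid) {
  v <- grid$values
  v[v == grid$nodata] <- NA_real_
  v
}

#' Build a grid sharing another grid's georeference
#'
#' @param grid template `raster_grid`.
#' @param values matrix of new values (`NA` allowed; converted to nodata).
#' @param layer_name label for the new layer.
#' @export
rg_like <- function(grid, values, layer_name = grid$layer_name) {
  raster_grid(values, grid$origin_lon, grid$origin_lat, grid$cell_size,
              grid$nodata, layer_name)
}

#' @rdname rg_values
#' @export
rg_is_nodata <- function(grid) grid$values == grid$nodata

#' Latitude / longitude of pixel centers
#'
#' @param grid a `raster_grid`.
#' @return `rg_lat_centers`: latitude (degrees) of each row center, north to
#'   south. `rg_lon_centers`: longitude of each column center, west to east.
#' @export
rg_lat_centers <- function(grid) {
  grid$origin_lat - (seq_len(nrow(grid$values)) - 0.5) * grid$cell_size
}

#' @rdname rg_lat_centers
#' @export
rg_lon_centers <- function(grid) {
  grid$origin_lon + (seq_len(ncol(grid$values)) - 0.5) * grid$cell_size
}

# TRUE when two grids share shape and georeference (within 1e-9 deg).
rg_same_geometry <- function(a, b) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$origin_lon - b$origin_lon) < 1e-9 &&
    abs(a$origin_lat - b$origin_lat) < 1e-9 &&
    abs(a$cell_size - b$cell_size) < 1e-12
}

.assert_registered <- function(..., what = "grids") {
  gs <- list(...)
  for (i in seq_along(gs)[-1]) {
    if (!rg_same_geometry(gs[[1]], gs[[i]]))
      stop(sprintf("%s are not co-registered (shape/georeference mismatch)", what))
  }
  invisible(TRUE)
}

#' Categorical grid over a declared class vocabulary
#'
#' Stores integer class codes (1-based into `levels`) in a `raster_grid`
#' with the vocabulary attached, so masking operations can validate codes
#' and report unknown classes by name.
#'
#' @param codes integer matrix of 1-based level codes (or a character matrix
#'   of level names).
#' @param levels character vector: the class vocabulary.
#' @inheritParams raster_grid
#' @export
categorical_grid <- function(codes, levels, origin_lon = 0, origin_lat = 0,
                             cell_size = 1 / 3600, nodata = -9999,
                             layer_name = "") {
  if (is.character(codes)) {
    m <- match(codes, levels)
    if (anyNA(m[!is.na(codes)]))
      stop("unknown class name(s): ",
           paste(unique(codes[is.na(m) & !is.na(codes)]), collapse = ", "))
    codes <- matrix(m, nrow(codes), ncol(codes))
  }
  g <- raster_grid(codes, origin_lon, origin_lat, cell_size, nodata, layer_name)
  attr(g, "levels") <- levels
  g
}

# Decode a categorical grid to a character matrix (NA where nodata),
# erroring on codes outside the vocabulary.
rg_classes <- function(grid) {
  lv <- attr(grid, "levels")
  if (is.null(lv)) stop("grid carries no class vocabulary")
  v <- rg_values(grid)
  ok <- is.na(v) | (v == round(v) & v >= 1 & v <= length(lv))
  if (!all(ok))
    stop("unknown class code(s): ",
         paste(unique(v[!ok]), collapse = ", "))
  matrix(lv[v], nrow(v), ncol(v))
}

#' Class vocabularies used by the pipeline
#'
#' `landcover_classes()` is the land-cover vocabulary of the synthetic scenes
#' and masking rules; `climate_classes()` is the climate-zone vocabulary
#' (dryland Koeppen-style groups `B` and the dry-summer temperate `Cs*`
#' classes, plus non-dryland catch-alls).
#' @export
landcover_classes <- function() {
  c("shrubland", "grassland", "barren", "cropland", "built", "water")
}

#' @rdname landcover_classes
#' @export
climate_classes <- function() {
  c("B", "Csa", "Csb", "Csc", "humid", "polar", "other")
}
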