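#' Raster, point-table and polygon I/O
#'
#' Rasters are stored in the plain-text ESRI ASCII grid format (`.asc`):
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of values from north to
#' south. Values are written with 17 significant digits so a write/read
#' round trip reproduces the grid bit-for-bit. Point tables are CSV with
#' header `lon,lat,label,source,region`; polygons are GeoJSON (WGS84).
#'
#' @param grid a [raster_grid()].
#' @param path file path.
#' @return `read_raster` returns a `raster_grid`; `write_raster` returns
#'   `path` invisibly.
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
write_raster <- function(grid, path) {
  v <- grid$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", grid$origin_lon),
    sprintf("yllcorner %.17g", grid$origin_lat - nrow(v) * grid$cell_size),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", grid$nodata))
  body <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 7) stop("parse error: truncated ASCII grid (header + data expected)")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("parse error in header line ", i, ": ", lines[i])
    key <- tolower(parts[1])
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) stop("parse error: non-numeric value for header field '", key, "'")
    hdr[[key]] <- val
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  missing <- setdiff(need, names(hdr))
  if (length(missing))
    stop("parse error: missing header field '", missing[1], "'")
  nr <- hdr$nrows; nc <- hdr$ncols
  body <- lines[-(1:6)]
  if (length(body) != nr)
    stop("parse error: field 'nrows' = ", nr, " but ", length(body), " data rows found")
  v <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(row) != nc || anyNA(row))
      stop("parse error: data row ", i, " does not hold ", nc, " numeric values")
    v[i, ] <- row
  }
  raster_grid(v, origin_lon = hdr$xllcorner,
              origin_lat = hdr$yllcorner + nr * hdr$cellsize,
              cell_size = hdr$cellsize, nodata = hdr$nodata_value,
              layer_name = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname raster_io
#' @param points data frame with columns `lon`, `lat` and optionally
#'   `label`, `source`, `region`.
#' @export
write_points <- function(points, path) {
  cols <- c("lon", "lat", "label", "source", "region")
  for (cn in setdiff(cols, names(points))) points[[cn]] <- NA
  utils::write.csv(points[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname raster_io
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("lon", "lat"))
    if (!cn %in% names(d)) stop("parse error: missing column '", cn, "'")
  if (!is.numeric(d$lon) || !is.numeric(d$lat))
    stop("parse error: columns 'lon'/'lat' must be numeric")
  for (cn in c("label", "source", "region"))
    if (!cn %in% names(d)) d[[cn]] <- NA_character_
  lab <- d$label[!is.na(d$label) & nzchar(d$label)]
  bad <- setdiff(unique(lab), c("GDE", "NONGDE"))
  if (length(bad))
    stop("parse error in column 'label': value(s) outside {GDE, NONGDE}: ",
         paste(bad, collapse = ", "))
  d$label[!is.na(d$label) & !nzchar(d$label)] <- NA_character_
  d[c("lon", "lat", "label", "source", "region")]
}

#' @rdname raster_io
#' @export
read_polygons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else if (identical(gj$type, "Feature")) list(gj)
           else stop("parse error: field 'type' must be Feature or FeatureCollection")
  zones <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    geom <- f$geometry
    if (is.null(geom$type)) stop("parse error: feature ", i, " has no geometry type")
    ring_list <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop("parse error: unsupported geometry type '", geom$type, "'"))
    rings <- lapply(ring_list, function(ring) {
      m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      if (nrow(m) < 4 || any(m[1, ] != m[nrow(m), ]))
        stop("parse error: polygon ring not closed in feature ", i)
      m
    })
    name <- f$properties$name
    if (is.null(name)) name <- paste0("zone_", i)
    list(name = name, rings = rings)
  })
  structure(zones, class = "polygon_set")
}

#' @rdname raster_io
#' @param zones a `polygon_set` as returned by `read_polygons`.
#' @export
write_polygons <- function(zones, path) {
  feats <- lapply(zones, function(z) {
    list(type = "Feature",
         properties = list(name = z$name),
         geometry = list(
           type = "Polygon",
           coordinates = lapply(z$rings, function(m)
             lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname raster_io
#' @param series a `storage_series` (see [generate_storage_series()]).
#' @export
write_storage_series <- function(series, path) {
  d <- data.frame(date = as.character(series$dates), tws = series$tws,
                  sm = series$sm, swe = series$swe, canopy = series$canopy)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_storage_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tws", "sm", "swe", "canopy")
  for (cn in need) if (!cn %in% names(d))
    stop("parse error: missing column '", cn, "'")
  structure(list(dates = as.Date(d$date), tws = d$tws, sm = d$sm,
                 swe = d$swe, canopy = d$canopy),
            class = "storage_series")
}

# Even-odd (ray casting) point-in-polygon over a set of rings; holes and
# multipolygon parts are handled uniformly by crossing parity. Points on a
# boundary resolve by the same parity rule.
.points_in_rings <- function(lon, lat, rings) {
  inside <- rep(FALSE, length(lon))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)  # ring is closed: last vertex repeats the first
    for (i in seq_len(n - 1)) {
      xi <- x[i]; yi <- y[i]; xj <- x[i + 1]; yj <- y[i + 1]
      if (yi == yj) next
      crosses <- ((yi > lat) != (yj > lat)) &
        (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
  }
  inside
}
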