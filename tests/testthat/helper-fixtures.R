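# Small fixture builders shared across the suite. Everything is generated
# in code; no data files.

grid_of <- function(values, nr = NULL, nc = NULL, origin_lat = 0, origin_lon = 0,
                    cell_size = 1 / 3600, nodata = -9999, name = "test") {
  if (!is.matrix(values)) values <- matrix(values, nr, nc, byrow = TRUE)
  raster_grid(values, origin_lon, origin_lat, cell_size, nodata, name)
}

# A single observation with constant bands, overridable per band.
obs_of <- function(nr = 3, nc = 3, date = as.Date("2016-08-15"),
                   red = 0.2, green = 0.15, nir = 0.4, swir1 = 0.3,
                   lst = 30, lst_uncert = 2, qa = "clear",
                   origin_lat = 35, cloud_fraction = 0) {
  mk <- function(x, name) {
    if (!is.matrix(x)) x <- matrix(x, nr, nc)
    grid_of(x, origin_lat = origin_lat, name = name)
  }
  qa_lv <- c("clear", "cloud", "shadow", "snow")
  qa_m <- if (is.matrix(qa)) qa else matrix(qa, nr, nc)
  structure(list(
    date = date, season = NA,
    red = mk(red, "red"), green = mk(green, "green"),
    nir = mk(nir, "nir"), swir1 = mk(swir1, "swir1"),
    lst = mk(lst, "lst"), lst_uncert = mk(lst_uncert, "lst_uncert"),
    qa = categorical_grid(matrix(match(qa_m, qa_lv), nr, nc), qa_lv,
                          origin_lon = 0, origin_lat = origin_lat,
                          cell_size = 1 / 3600, layer_name = "qa"),
    scene_cloud_fraction = cloud_fraction), class = "scene_observation")
}

# Dated index items for dry_season_stats from a list of (date, matrix).
items_of <- function(..., origin_lat = 35) {
  lapply(list(...), function(x)
    list(date = as.Date(x[[1]]),
         grid = grid_of(x[[2]], origin_lat = origin_lat)))
}

# Minimal predictor stack: the 11 canonical layers filled from a named
# list of matrices (defaults to zeros).
stack_of <- function(layers = list(), nr = 3, nc = 3, origin_lat = 35) {
  out <- list()
  for (nm in predictor_names()) {
    v <- if (nm %in% names(layers)) layers[[nm]] else matrix(0, nr, nc)
    out[[nm]] <- grid_of(v, origin_lat = origin_lat, name = nm)
  }
  assemble_predictors(out)
}

# Two well-separated Gaussian point clouds as a labelled point table plus
# a stack whose first two layers carry the signal.
separable_points <- function(n_per_class = 60, seed = 1, sep = 6, nr = 30, nc = 30) {
  set.seed(seed)
  cs <- 1 / 3600
  # place points at distinct pixel centers of an nr x nc grid
  idx <- sample(nr * nc, 2 * n_per_class)
  row <- ((idx - 1) %% nr) + 1
  col <- ((idx - 1) %/% nr) + 1
  label <- rep(c("GDE", "NONGDE"), each = n_per_class)
  pts <- data.frame(lon = (col - 0.5) * cs, lat = 35 - (row - 0.5) * cs,
                    label = label, source = "sim",
                    region = rep(c("A", "B"), length.out = 2 * n_per_class),
                    stringsAsFactors = FALSE)
  f1 <- matrix(rnorm(nr * nc), nr, nc)
  f2 <- matrix(rnorm(nr * nc), nr, nc)
  pix <- cbind(row, col)
  f1[pix] <- f1[pix] + ifelse(label == "GDE", sep / 2, -sep / 2)
  f2[pix] <- f2[pix] + ifelse(label == "GDE", -sep / 2, sep / 2)
  stack <- stack_of(list(ndvi_mean = f1, etap = f2), nr = nr, nc = nc,
                    origin_lat = 35)
  list(points = pts, stack = stack)
}

# Per-tree vote-counting oracle for the trained ensemble.
vote_fraction_oracle <- function(model, newdata) {
  rf <- model$rf
  ntree <- rf$ntree
  vote_one <- function(k, row) {
    tr <- randomForest::getTree(rf, k, labelVar = TRUE)
    node <- 1
    repeat {
      if (tr[node, "status"] == -1) return(as.character(tr[node, "prediction"]))
      v <- row[[as.character(tr[node, "split var"])]]
      node <- if (v <= tr[node, "split point"]) tr[node, "left daughter"]
              else tr[node, "right daughter"]
    }
  }
  vapply(seq_len(nrow(newdata)), function(i)
    mean(vapply(seq_len(ntree), function(k)
      vote_one(k, newdata[i, , drop = FALSE]), "") == "GDE"), 0)
}

# Brute-force circular focal mean.
focal_mean_oracle <- function(v, radius, fill_only = FALSE) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -floor(radius):floor(radius))
      for (dj in -floor(radius):floor(radius)) {
        if (di^2 + dj^2 > radius^2) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (!is.na(v[ii, jj])) vals <- c(vals, v[ii, jj])
      }
    if (length(vals)) out[i, j] <- mean(vals)
  }
  if (fill_only) out[!is.na(v)] <- v[!is.na(v)]
  out
}
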