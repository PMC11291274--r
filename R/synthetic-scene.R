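#' Scenario configuration for synthetic dryland scenes
#'
#' Defines the conditions a generated landscape emulates: GDE "islands"
#' that stay green and wet through the dry season, run cooler than their
#' surroundings, transpire more than the local precipitation and sit over
#' shallow water tables, embedded in a xeric matrix with clouds, QA
#' dropouts and sensor noise. `contrast` is the dimensionless signal
#' separation between GDE and matrix pixels: 0 makes GDE pixels
#' statistically identical to the matrix; the default of 2 shifts
#' dry-season NIR up and SWIR1 down by `2 * noise_sd` reflectance units,
#' cools GDE pixels by `2 * delta_t` degrees C and raises the GDE
#' transpiration:precipitation ratio from 0.8 to 1.4.
#'
#' @param n_rows,n_cols scene size in pixels.
#' @param cell_size pixel size in degrees (default 1 arcsecond, roughly
#'   30 m).
#' @param origin_lon,origin_lat north-west corner, degrees.
#' @param n_years number of observation years (dry-season compositing and
#'   interannual CV need at least 2).
#' @param obs_per_season clear-sky observations generated per season per
#'   year (dry and wet seasons are both emitted, so compositing must select).
#' @param gde_fraction target fraction of the scene covered by true GDE
#'   patches.
#' @param patch_geometry mix weights for `riparian_corridor`, `spring_disc`
#'   and `phreatophyte_patch` geometries.
#' @param contrast signal separation (>= 0, dimensionless).
#' @param delta_t GDE cooling in degrees C per unit contrast.
#' @param cloud_prob per-pixel cloud probability in each scene.
#' @param lst_uncert_sd spread of the per-pixel LST uncertainty layer, deg C.
#' @param noise_sd reflectance noise standard deviation (reflectance units).
#' @param dtg_range range (m) of matrix depth-to-groundwater values.
#' @param barren_fraction,cropland_fraction,built_fraction,water_fraction,
#'   humid_fraction approximate fractions of the scene assigned to barren
#'   land cover, masked land-cover classes and a non-dryland climate pocket
#'   (all painted on non-GDE pixels so masking never removes truth).
#' @param region_rows,region_cols grid partition used to tag points with
#'   region labels for regional cross-validation.
#' @param region_contrast optional per-region contrast overrides (vector of
#'   length `region_rows * region_cols`); NA entries fall back to `contrast`.
#' @param n_cloudy_scenes extra heavily clouded dry-season scenes per
#'   bundle, exercising the scene-level cloud screen.
#' @param storage_trend,storage_seasonal_amp,storage_noise_sd,storage_months
#'   parameters of the bundled groundwater storage series (cm/yr, cm, cm,
#'   months).
#' @param seed master seed; each generator component draws from its own
#'   stream derived from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_rows = 200, n_cols = 200,
                            cell_size = 1 / 3600,
                            origin_lon = 22, origin_lat = 35,
                            n_years = 3, obs_per_season = 3,
                            gde_fraction = 0.1,
                            patch_geometry = c(riparian_corridor = 0.4,
                                               spring_disc = 0.2,
                                               phreatophyte_patch = 0.4),
                            contrast = 2, delta_t = 2,
                            cloud_prob = 0.05, lst_uncert_sd = 1.5,
                            noise_sd = 0.02, dtg_range = c(0, 100),
                            barren_fraction = 0.10, cropland_fraction = 0.03,
                            built_fraction = 0.02, water_fraction = 0.02,
                            humid_fraction = 0.03,
                            region_rows = 2, region_cols = 2,
                            region_contrast = NULL,
                            n_cloudy_scenes = 1,
                            storage_trend = -0.5, storage_seasonal_amp = 2,
                            storage_noise_sd = 1, storage_months = 241,
                            seed = 1) {
  stopifnot(n_rows >= 10, n_cols >= 10, cell_size > 0, n_years >= 1,
            obs_per_season >= 1)
  if (gde_fraction < 0 || gde_fraction > 1) stop("gde_fraction must be in [0, 1]")
  if (contrast < 0) stop("contrast must be >= 0")
  for (p in c(cloud_prob, barren_fraction, cropland_fraction, built_fraction,
              water_fraction, humid_fraction))
    if (p < 0 || p > 1) stop("all probabilities/fractions must be in [0, 1]")
  if (!is.null(region_contrast) &&
      length(region_contrast) != region_rows * region_cols)
    stop("region_contrast must have length region_rows * region_cols")
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

# Component seeds derived from the master seed so that adding a component
# never perturbs the streams of the others. Kept below 2^31.
.sub_seed <- function(seed, k) (abs(seed) %% 20000000L) * 100L + k

# ---- patch geometry generators (pixel index sets) ------------------------

.patch_corridor <- function(nr, nc) {
  # random-walk polyline entering from a random edge, dilated to width 1-3 px
  width <- sample(1:3, 1)
  side <- sample(1:4, 1)
  pos <- switch(side,
    c(1, sample(nc, 1)), c(nr, sample(nc, 1)),
    c(sample(nr, 1), 1), c(sample(nr, 1), nc))
  drift <- switch(side, c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  steps <- sample(floor(0.5 * max(nr, nc)):(max(nr, nc)), 1)
  path <- matrix(NA_integer_, steps, 2)
  for (s in seq_len(steps)) {
    path[s, ] <- pos
    jitter <- sample(-1:1, 2, replace = TRUE)
    pos <- pos + drift + jitter
    pos[1] <- min(max(pos[1], 1), nr); pos[2] <- min(max(pos[2], 1), nc)
  }
  r <- width - 1
  cells <- unique(do.call(rbind, lapply(seq_len(steps), function(s) {
    dr <- rep(-r:r, each = 2 * r + 1); dc <- rep(-r:r, times = 2 * r + 1)
    cbind(path[s, 1] + dr, path[s, 2] + dc)
  })))
  cells <- cells[cells[, 1] >= 1 & cells[, 1] <= nr &
                 cells[, 2] >= 1 & cells[, 2] <= nc, , drop = FALSE]
  unique(cells[, 1] + (cells[, 2] - 1) * nr)
}

.patch_disc <- function(nr, nc) {
  r <- sample(1:2, 1)
  ctr <- c(sample(nr, 1), sample(nc, 1))
  dr <- rep(-r:r, each = 2 * r + 1); dc <- rep(-r:r, times = 2 * r + 1)
  keep <- dr^2 + dc^2 <= r^2
  cells <- cbind(ctr[1] + dr[keep], ctr[2] + dc[keep])
  cells <- cells[cells[, 1] >= 1 & cells[, 1] <= nr &
                 cells[, 2] >= 1 & cells[, 2] <= nc, , drop = FALSE]
  unique(cells[, 1] + (cells[, 2] - 1) * nr)
}

.patch_blob <- function(nr, nc) {
  # smoothed-noise threshold blob dropped at a random center
  sz <- 25
  f <- .box_mean(.box_mean(matrix(stats::rnorm(sz * sz), sz, sz), 2), 2)
  q <- stats::quantile(f, stats::runif(1, 0.80, 0.95))
  idx <- which(f >= q, arr.ind = TRUE)
  ctr <- c(sample(nr, 1), sample(nc, 1))
  cells <- cbind(ctr[1] + idx[, 1] - (sz + 1) %/% 2,
                 ctr[2] + idx[, 2] - (sz + 1) %/% 2)
  cells <- cells[cells[, 1] >= 1 & cells[, 1] <= nr &
                 cells[, 2] >= 1 & cells[, 2] <= nc, , drop = FALSE]
  unique(cells[, 1] + (cells[, 2] - 1) * nr)
}

# Paint approximately `frac * n` pixels of a class as random rectangles,
# skipping forbidden pixels. Returns updated code matrix.
.paint_patches <- function(codes, class_code, frac, forbid) {
  nr <- nrow(codes); nc <- ncol(codes)
  target <- round(frac * nr * nc)
  painted <- 0; tries <- 0
  while (painted < target && tries < 200) {
    tries <- tries + 1
    h <- sample(3:max(3, round(nr / 8)), 1)
    w <- sample(3:max(3, round(nc / 8)), 1)
    r0 <- sample(nr - h + 1, 1); c0 <- sample(nc - w + 1, 1)
    rows <- r0:(r0 + h - 1); cols <- c0:(c0 + w - 1)
    blk <- codes[rows, cols]
    ok <- !forbid[rows, cols]
    need <- target - painted
    sel <- which(ok & blk != class_code)
    if (length(sel) > need) sel <- sel[seq_len(need)]
    blk[sel] <- class_code
    codes[rows, cols] <- blk
    painted <- painted + length(sel)
  }
  codes
}

#' Generate a synthetic dryland scene
#'
#' Builds a complete `scene_bundle`: terrain, truth mask, land cover,
#' climate classes, depth to groundwater, dated spectral/thermal
#' observations for dry and wet seasons over `n_years`, monthly
#' precipitation and transpiration forcing, a region partition and a
#' groundwater storage series. Deterministic for a fixed config and seed.
#'
#' @param config a [scenario_config()].
#' @return An object of class `scene_bundle`.
#' @export
generate_scene <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  nr <- config$n_rows; nc <- config$n_cols; n <- nr * nc
  gridder <- function(v, name) raster_grid(matrix(v, nr, nc), config$origin_lon,
                                           config$origin_lat, config$cell_size,
                                           layer_name = name)

  # region partition and per-pixel contrast
  rr <- ceiling(seq_len(nr) / (nr / config$region_rows))
  cc <- ceiling(seq_len(nc) / (nc / config$region_cols))
  region_id <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) region_id[i, ] <- (rr[i] - 1L) * config$region_cols + cc
  region_levels <- paste0("R", seq_len(config$region_rows * config$region_cols))
  contrast_px <- matrix(config$contrast, nr, nc)
  if (!is.null(config$region_contrast)) {
    rcst <- config$region_contrast
    rcst[is.na(rcst)] <- config$contrast
    contrast_px[] <- rcst[region_id]
  }

  # terrain
  set.seed(.sub_seed(config$seed, 1))
  tilt <- outer(seq_len(nr), seq_len(nc),
                function(i, j) 0.3 * i + 0.15 * j)
  dem <- 500 + 60 * .smooth_field(nr, nc) + tilt

  # truth mask from patch geometries, trimmed to the exact target count
  set.seed(.sub_seed(config$seed, 2))
  target <- round(config$gde_fraction * n)
  truth <- rep(FALSE, n)
  if (target < 1) {
    if (config$gde_fraction > 0)
      warning("gde_fraction times extent is below one pixel; truth mask is empty")
  } else {
    w <- config$patch_geometry / sum(config$patch_geometry)
    guard <- 0
    while (sum(truth) < target && guard < 10000) {
      guard <- guard + 1
      kind <- sample(names(w), 1, prob = w)
      cells <- switch(kind,
        riparian_corridor = .patch_corridor(nr, nc),
        spring_disc = .patch_disc(nr, nc),
        phreatophyte_patch = .patch_blob(nr, nc))
      new <- cells[!truth[cells]]
      need <- target - sum(truth)
      if (length(new) > need) new <- sample(new, need)
      truth[new] <- TRUE
    }
  }
  truth_m <- matrix(truth, nr, nc)

  # land cover: coherent shrubland/grassland matrix, then special classes
  # painted on non-GDE pixels only (so the extent always contains the truth)
  set.seed(.sub_seed(config$seed, 3))
  lv <- landcover_classes()
  base <- ifelse(.smooth_field(nr, nc) > 0, match("shrubland", lv),
                 match("grassland", lv))
  codes <- matrix(base, nr, nc)
  codes <- .paint_patches(codes, match("barren", lv), config$barren_fraction, truth_m)
  codes <- .paint_patches(codes, match("cropland", lv), config$cropland_fraction, truth_m)
  codes <- .paint_patches(codes, match("built", lv), config$built_fraction, truth_m)
  codes <- .paint_patches(codes, match("water", lv), config$water_fraction, truth_m)
  landcover <- categorical_grid(codes, lv, config$origin_lon, config$origin_lat,
                                config$cell_size, layer_name = "landcover")

  clv <- climate_classes()
  ccodes <- matrix(match("B", clv), nr, nc)
  ccodes <- .paint_patches(ccodes, match("humid", clv), config$humid_fraction, truth_m)
  climate <- categorical_grid(ccodes, clv, config$origin_lon, config$origin_lat,
                              config$cell_size, layer_name = "climate_class")

  # depth to groundwater: deep-tailed matrix, shallow under GDE patches
  set.seed(.sub_seed(config$seed, 4))
  dr <- config$dtg_range
  dtg <- dr[1] + (dr[2] - dr[1]) * stats::pnorm(.smooth_field(nr, nc) +
                                                0.5 * stats::rnorm(n))
  dtg[truth_m] <- stats::runif(sum(truth_m), 0.5, min(15, 30))
  # water pixels mimic the gaps of real DTG products
  wat <- codes == match("water", lv)
  dtg_g <- gridder(dtg, "dtg")
  vdtg <- dtg_g$values; vdtg[wat] <- dtg_g$nodata; dtg_g$values <- vdtg

  hemisphere_north <- config$origin_lat >= 0
  years <- 2015:(2015 + config$n_years - 1)

  # spectral/thermal observations
  set.seed(.sub_seed(config$seed, 5))
  base_refl <- list(
    dry = c(red = 0.20, green = 0.15, nir = 0.25, swir1 = 0.35),
    wet = c(red = 0.15, green = 0.13, nir = 0.33, swir1 = 0.26))
  # GDE departures per unit contrast, in units of noise_sd
  gde_shift <- c(red = -0.5, green = 0.25, nir = 1, swir1 = -1)
  obs_dates <- function(y, season) {
    months <- if (season == "dry") {
      if (hemisphere_north) 7:9 else 1:3
    } else {
      if (hemisphere_north) 1:3 else 7:9
    }
    day <- round(seq(8, 24, length.out = config$obs_per_season))
    m <- rep(months, length.out = config$obs_per_season)
    as.Date(sprintf("%d-%02d-%02d", y, m, day))
  }
  spatial_refl <- 0.01 * .smooth_field(nr, nc)
  lst_field <- 1.5 * .smooth_field(nr, nc)

  make_obs <- function(date, season, cloud_prob) {
    eff <- contrast_px * config$noise_sd * ifelse(truth_m, 1, 0) *
      if (season == "dry") 1 else 0.25
    qa_code <- sample.int(3L, n, replace = TRUE,
                          prob = c(1 - 1.5 * cloud_prob, cloud_prob, 0.5 * cloud_prob))
    qa_lv <- c("clear", "cloud", "shadow", "snow")
    cloudy <- matrix(qa_code != 1L, nr, nc)
    bands <- lapply(names(base_refl[[season]]), function(b) {
      v <- base_refl[[season]][[b]] + spatial_refl + gde_shift[[b]] * eff +
        config$noise_sd * matrix(stats::rnorm(n), nr, nc)
      v[cloudy] <- stats::runif(sum(cloudy), 0.45, 0.7)
      gridder(pmin(pmax(v, 0), 1), b)
    })
    names(bands) <- names(base_refl[[season]])
    lst_base <- if (season == "dry") 38 else 26
    lst <- lst_base + lst_field - config$delta_t * contrast_px *
      ifelse(truth_m, 1, 0) * (if (season == "dry") 1 else 0.3) +
      0.8 * matrix(stats::rnorm(n), nr, nc)
    lst[cloudy] <- lst[cloudy] - 12
    lst_unc <- abs(2 + config$lst_uncert_sd * matrix(stats::rnorm(n), nr, nc))
    structure(list(date = date, season = season,
                   red = bands$red, green = bands$green, nir = bands$nir,
                   swir1 = bands$swir1,
                   lst = gridder(lst, "lst"),
                   lst_uncert = gridder(lst_unc, "lst_uncert"),
                   qa = categorical_grid(matrix(qa_code, nr, nc), qa_lv,
                                         config$origin_lon, config$origin_lat,
                                         config$cell_size, layer_name = "qa"),
                   scene_cloud_fraction = mean(qa_code != 1L)),
              class = "scene_observation")
  }

  observations <- list()
  for (y in years) {
    for (season in c("dry", "wet")) {
      for (d in seq_len(config$obs_per_season)) {
        date <- obs_dates(y, season)[d]
        observations[[length(observations) + 1]] <- make_obs(date, season,
                                                             config$cloud_prob)
      }
    }
  }
  if (config$n_cloudy_scenes > 0) {
    for (k in seq_len(config$n_cloudy_scenes)) {
      date <- obs_dates(years[1], "dry")[1] + k  # extra cloudy revisit
      observations[[length(observations) + 1]] <- make_obs(date, "dry", 0.4)
    }
  }
  ord <- order(vapply(observations, function(o) as.numeric(o$date), 0))
  observations <- observations[ord]

  # monthly climate forcing: winter-peaked precipitation; transpiration set
  # by a per-pixel annual ratio (matrix 0.8, GDE 0.8 + 0.3 * contrast)
  set.seed(.sub_seed(config$seed, 6))
  month_weight <- if (hemisphere_north) {
    c(0.16, 0.14, 0.12, 0.08, 0.05, 0.03, 0.02, 0.02, 0.03, 0.08, 0.12, 0.15)
  } else {
    c(0.02, 0.02, 0.03, 0.08, 0.12, 0.15, 0.16, 0.14, 0.12, 0.08, 0.05, 0.03)
  }
  annual_precip <- 300 * (1 + 0.1 * .smooth_field(nr, nc))
  ratio_px <- 0.8 + 0.3 * contrast_px * ifelse(truth_m, 1, 0) +
    0.05 * matrix(stats::rnorm(n), nr, nc)
  precip <- list(); transp <- list()
  for (y in years) for (m in 1:12) {
    key <- sprintf("%d-%02d", y, m)
    p <- annual_precip * month_weight[m] *
      (1 + 0.1 * matrix(stats::rnorm(n), nr, nc))
    p <- pmax(p, 0)
    precip[[key]] <- gridder(p, paste0("precip_", key))
    tr <- pmax(ratio_px * p * (1 + 0.05 * matrix(stats::rnorm(n), nr, nc)), 0)
    transp[[key]] <- gridder(tr, paste0("transp_", key))
  }

  storage <- generate_storage_series(
    trend = config$storage_trend, seasonal_amp = config$storage_seasonal_amp,
    noise_sd = config$storage_noise_sd, n_months = config$storage_months,
    seed = .sub_seed(config$seed, 7))

  structure(list(
    config = config,
    dem = gridder(dem, "dem"),
    dtg = dtg_g,
    landcover = landcover,
    climate_class = climate,
    truth = gridder(as.numeric(truth_m), "truth"),
    region = categorical_grid(region_id, region_levels, config$origin_lon,
                              config$origin_lat, config$cell_size,
                              layer_name = "region"),
    contrast = gridder(contrast_px, "contrast"),
    observations = observations,
    precip = precip,
    transp = transp,
    years = years,
    storage = storage), class = "scene_bundle")
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf("<scene_bundle> %d x %d px, %d observations over %d year(s), %d truth pixels\n",
              nrow(x$truth$values), ncol(x$truth$values), length(x$observations),
              length(x$years), sum(x$truth$values == 1)))
  invisible(x)
}

#' Sample labelled training/validation points from a scene
#'
#' Draws `n_gde` points uniformly from true GDE pixels (label `GDE`),
#' `n_nongde` from non-GDE, non-barren pixels of the analysis extent
#' (label `NONGDE`) and `n_barren` from barren land cover (label `NONGDE`,
#' mirroring the use of randomly sampled barren areas as additional
#' negatives). Points take their region tag from the bundle's partition.
#'
#' @param bundle a `scene_bundle`.
#' @param n_gde,n_nongde,n_barren stratum sizes.
#' @param seed RNG seed for the draw.
#' @return A point table (data frame with `lon`, `lat`, `label`, `source`,
#'   `region`).
#' @export
sample_points <- function(bundle, n_gde, n_nongde, n_barren = 0, seed = 1) {
  stopifnot(inherits(bundle, "scene_bundle"))
  ext <- rg_values(.bundle_extent(bundle)$extent)
  truth <- bundle$truth$values == 1
  lc <- rg_classes(bundle$landcover)
  in_ext <- !is.na(ext) & ext == 1
  strata <- list(
    gde = which(truth),
    nongde = which(in_ext & !truth & lc != "barren"),
    barren = which(in_ext & !truth & lc == "barren"))
  want <- c(gde = n_gde, nongde = n_nongde, barren = n_barren)
  for (s in names(want)) {
    if (want[[s]] > length(strata[[s]]))
      stop(sprintf("stratum '%s' exhausted: %d points requested, %d available",
                   s, want[[s]], length(strata[[s]])))
  }
  set.seed(seed)
  pick <- function(idx, k) if (k > 0) sample(idx, k) else integer(0)
  sel <- list(gde = pick(strata$gde, n_gde),
              nongde = pick(strata$nongde, n_nongde),
              barren = pick(strata$barren, n_barren))
  nr <- nrow(bundle$truth$values)
  reg_lv <- attr(bundle$region, "levels")
  mk <- function(idx, label, source) {
    if (!length(idx)) return(NULL)
    row <- ((idx - 1) %% nr) + 1
    col <- ((idx - 1) %/% nr) + 1
    data.frame(
      lon = bundle$truth$origin_lon + (col - 0.5) * bundle$truth$cell_size,
      lat = bundle$truth$origin_lat - (row - 0.5) * bundle$truth$cell_size,
      label = label, source = source,
      region = reg_lv[bundle$region$values[idx]],
      stringsAsFactors = FALSE)
  }
  pts <- rbind(mk(sel$gde, "GDE", "simulated_gde"),
               mk(sel$nongde, "NONGDE", "simulated_matrix"),
               mk(sel$barren, "NONGDE", "barren_sample"))
  rownames(pts) <- NULL
  pts
}

#' Generate a synthetic groundwater storage series
#'
#' Monthly anomalies (cm equivalent water thickness): the groundwater
#' component is a linear trend plus an annual sinusoid plus white noise;
#' soil moisture, snow water equivalent and canopy storage are independent
#' zero-trend seasonal-plus-noise series; total water storage is their
#' exact sum, so subtracting the three components recovers the groundwater
#' anomaly to machine precision. The true series and trend are kept in the
#' object for recovery tests.
#'
#' @param trend groundwater trend, cm per year.
#' @param seasonal_amp amplitude of the annual cycle, cm.
#' @param noise_sd white-noise standard deviation, cm.
#' @param n_months series length (>= 24).
#' @param seed RNG seed.
#' @param start_date first month (the 20-year window of interest starts
#'   April 2002).
#' @return A `storage_series` with elements `dates`, `tws`, `sm`, `swe`,
#'   `canopy`, `gws_true`, `trend_true`.
#' @export
generate_storage_series <- function(trend, seasonal_amp = 2, noise_sd = 1,
                                    n_months = 241, seed = 1,
                                    start_date = as.Date("2002-04-15")) {
  if (n_months < 24) stop("n_months must be >= 24")
  set.seed(seed)
  dates <- seq(start_date, by = "month", length.out = n_months)
  # time axis in calendar (365.25-day) years, matching how trends are fit
  t_yr <- as.numeric(dates - dates[1]) / 365.25
  gws <- trend * t_yr + seasonal_amp * sin(2 * pi * t_yr) +
    noise_sd * stats::rnorm(n_months)
  comp <- function(amp, phase, sd) {
    amp * sin(2 * pi * t_yr + phase) + sd * stats::rnorm(n_months)
  }
  sm <- comp(1.5, pi / 3, 0.5 * noise_sd)
  swe <- comp(0.5, pi / 2, 0.2 * noise_sd)
  canopy <- comp(0.1, 0, 0.05 * noise_sd)
  structure(list(dates = dates, tws = gws + sm + swe + canopy,
                 sm = sm, swe = swe, canopy = canopy,
                 gws_true = gws, trend_true = trend),
            class = "storage_series")
}

#' @export
print.storage_series <- function(x, ...) {
  cat(sprintf("<storage_series> %d months, %s to %s\n", length(x$dates),
              min(x$dates), max(x$dates)))
  invisible(x)
}
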