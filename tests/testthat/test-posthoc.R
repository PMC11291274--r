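test_that("storage decomposition is the exact linear identity", {
  s <- generate_storage_series(trend = -0.3, seasonal_amp = 1.5, noise_sd = 0.8,
                               n_months = 60, seed = 3)
  g <- gws_anomaly(s)
  expect_equal(g$gws, s$gws_true, tolerance = 1e-12)

  s2 <- s; s2$sm <- s2$sm * 0; s2$swe <- s2$swe * 0; s2$canopy <- s2$canopy * 0
  expect_equal(gws_anomaly(s2)$gws, s2$tws)

  one <- structure(list(dates = as.Date("2010-01-15"), tws = 10, sm = 3,
                        swe = 2, canopy = 1), class = "storage_series")
  expect_equal(gws_anomaly(one)$gws, 4)

  bad <- s; bad$sm <- bad$sm[-1]
  expect_error(gws_anomaly(bad), "misaligned")
})

test_that("OLS trend is exact on lines, bounded under seasonality, windowed", {
  d <- seq(as.Date("2002-04-15"), by = "month", length.out = 241)
  t_yr <- as.numeric(d - d[1]) / 365.25
  expect_equal(ols_trend(-1.2 * t_yr + 3, d)$slope, -1.2, tolerance = 1e-9)

  # annual sinusoid on top of the line: equals the lm() oracle exactly and
  # contaminates the slope by well under 1% of the amplitude
  v <- -1.2 * t_yr + 2 * sin(2 * pi * (0:240) / 12)
  tr <- ols_trend(v, d)
  oracle <- unname(coef(lm(v ~ t_yr))[2])
  expect_equal(tr$slope, oracle, tolerance = 1e-12)
  expect_lt(abs(tr$slope + 1.2), 0.01 * 2)

  # window restriction drops out-of-range months from the fit
  d2 <- seq(as.Date("2000-01-15"), by = "month", length.out = 320)
  t2 <- as.numeric(d2 - d2[1]) / 365.25
  v2 <- 2 * t2
  v2[d2 < as.Date("2002-04-01")] <- 100   # junk outside the window
  expect_equal(ols_trend(v2, d2)$slope, 2, tolerance = 1e-9)
  expect_error(ols_trend(v2[1:23], d2[1:23], window = NULL), "24")
})

test_that("declining-area fraction weights density by geodesic area", {
  dens <- grid_of(matrix(1, 2, 2))
  tr_all_neg <- trend_grid(grid_of(matrix(-1, 2, 2)))
  expect_equal(fraction_declining(dens, tr_all_neg), 1)

  dens2 <- grid_of(matrix(c(0.5, 0.5, 0, 0), 2, 2, byrow = TRUE))
  tr2 <- trend_grid(grid_of(matrix(c(-1, 1, -1, 1), 2, 2, byrow = TRUE)))
  expect_equal(fraction_declining(dens2, tr2), 0.5, tolerance = 1e-9)

  # masked trend cells leave numerator and denominator
  tr3 <- trend_grid(grid_of(matrix(c(-1, NA, -1, 1), 2, 2, byrow = TRUE)))
  expect_equal(fraction_declining(dens2, tr3), 1)

  # invariance under uniform density rescaling
  dens3 <- grid_of(matrix(c(0.1, 0.5, 0, 0), 2, 2, byrow = TRUE))
  dens3_scaled <- grid_of(0.2 * matrix(c(0.1, 0.5, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(fraction_declining(dens3, tr2),
               fraction_declining(dens3_scaled, tr2))

  expect_error(fraction_declining(grid_of(matrix(0, 2, 2)), tr2), "no GDE area")
})

test_that("zonal means are area-weighted over cell centers", {
  sq <- function(lon0, lat0, lon1, lat1) {
    list(name = "z", rings = list(cbind(c(lon0, lon1, lon1, lon0, lon0),
                                        c(lat0, lat0, lat1, lat1, lat0))))
  }
  zones <- structure(list(sq(0, -3, 3, 0)), class = "polygon_set")
  const <- grid_of(matrix(4.2, 3, 3), cell_size = 1, origin_lat = 0)
  zc <- zonal_area_weighted_mean(const, zones)
  expect_equal(zc$mean, 4.2)
  expect_equal(zc$n_cells, 9)

  # two equal-area cells valued 2 and 4 -> 3
  g2 <- grid_of(matrix(c(2, 4), 1, 2), cell_size = 1, origin_lat = 0.5)
  z2 <- structure(list(sq(0, -0.5, 2, 0.5)), class = "polygon_set")
  expect_equal(zonal_area_weighted_mean(g2, z2)$mean, 3, tolerance = 1e-6)

  # unequal-area cells at high latitude: weights follow the zone formula
  gg <- grid_of(matrix(c(1, 0), 2, 1), cell_size = 1, origin_lat = 61)
  zz <- structure(list(sq(-1, 58, 2, 62)), class = "polygon_set")
  zres <- zonal_area_weighted_mean(gg, zz)
  a1 <- cell_area_km2(60.5, 1); a2 <- cell_area_km2(59.5, 1)
  expect_equal(zres$mean, a1 / (a1 + a2), tolerance = 1e-9)
  # sanity: the 0-vs-60-degree pair of the classic example gives ~1/3
  expect_equal(cell_area_km2(60, 1) / (cell_area_km2(0, 1) + cell_area_km2(60, 1)),
               1 / 3, tolerance = 0.01)

  # empty zone reports NA
  zempty <- structure(list(sq(50, 50, 51, 51)), class = "polygon_set")
  expect_true(is.na(zonal_area_weighted_mean(const, zempty)$mean))
})

test_that("protection categories partition mapped GDE area", {
  b <- matrix(2, 3, 3)
  b[1, 1] <- 1; b[1, 2] <- 1; b[2, 1] <- 1; b[2, 2] <- 1
  pa <- matrix(0, 3, 3); pa[1, 1] <- 1; pa[2, 2] <- 1
  po <- matrix(0, 3, 3); po[1, 2] <- 1; po[2, 2] <- 1
  pf <- protection_fraction(grid_of(b), grid_of(pa), grid_of(po))
  expect_equal(pf$protected_area_only, 0.25, tolerance = 1e-9)
  expect_equal(pf$policy_only, 0.25, tolerance = 1e-9)
  expect_equal(pf$both, 0.25, tolerance = 1e-9)
  expect_equal(pf$unprotected, 0.25, tolerance = 1e-9)
  expect_equal(pf$any, 0.75, tolerance = 1e-9)
  expect_equal(pf$unprotected + pf$protected_area_only + pf$policy_only + pf$both, 1)

  none <- protection_fraction(grid_of(b), grid_of(matrix(0, 3, 3)),
                              grid_of(matrix(0, 3, 3)))
  expect_equal(none$unprotected, 1)
  all_in <- protection_fraction(grid_of(b), grid_of(matrix(1, 3, 3)),
                                grid_of(matrix(1, 3, 3)))
  expect_equal(all_in$both, 1)
  expect_equal(all_in$any, 1)
  expect_error(protection_fraction(grid_of(matrix(2, 2, 2)),
                                   grid_of(matrix(0, 2, 2)),
                                   grid_of(matrix(0, 2, 2))), "no GDE pixels")
})

test_that("threshold overlap uses strict exceedance and drops covariate nodata", {
  dens <- grid_of(matrix(0.2, 2, 2))
  cov1 <- grid_of(matrix(1, 2, 2))
  expect_equal(threshold_overlap(dens, cov1, 0.25), 1)
  cov_eq <- grid_of(matrix(0.25, 2, 2))
  expect_equal(threshold_overlap(dens, cov_eq, 0.25), 0)

  cov <- grid_of(matrix(c(0.3, 0.3, 0.1, NA), 2, 2, byrow = TRUE))
  expect_equal(threshold_overlap(dens, cov, 0.25), 2 / 3, tolerance = 1e-6)
})
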