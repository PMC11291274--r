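test_that("quality screening applies scene-level and pixel-level rules", {
  o_bad <- obs_of(cloud_fraction = 0.21)
  o_edge <- obs_of(cloud_fraction = 0.20)
  expect_length(qa_screen(list(o_bad, o_edge)), 1)

  qa <- matrix("clear", 3, 3); qa[2, 1] <- "cloud"
  o <- obs_of(qa = qa, nir = 0.4)
  s <- qa_screen(list(o))[[1]]
  nir <- rg_values(s$nir)
  expect_true(is.na(nir[2, 1]))
  expect_equal(sum(is.na(nir)), 1)

  unc <- matrix(2, 3, 3); unc[1, 3] <- 5.0; unc[3, 3] <- 5.1
  s2 <- qa_screen(list(obs_of(lst_uncert = unc)))[[1]]
  lst <- rg_values(s2$lst)
  expect_false(is.na(lst[1, 3]))   # exactly 5 degC retained
  expect_true(is.na(lst[3, 3]))    # strictly greater dropped
})

test_that("spectral indices match their closed forms and degenerate rules", {
  o <- obs_of(nir = 0.3, red = 0.3)
  expect_equal(rg_values(spectral_index(o, "NDVI"))[1, 1], 0)

  o2 <- obs_of(nir = 0.5, red = 0.1, green = 0.2, swir1 = 0.3)
  expect_equal(rg_values(spectral_index(o2, "NDVI"))[1, 1], 0.4 / 0.6,
               tolerance = 1e-6)
  expect_equal(rg_values(spectral_index(o2, "NDMI"))[1, 1], 0.2 / 0.8)
  expect_equal(rg_values(spectral_index(o2, "NDWI"))[1, 1], -0.3 / 0.7)
  msavi <- (2 * 0.5 + 1 - sqrt((2 * 0.5 + 1)^2 - 8 * (0.5 - 0.1))) / 2
  expect_equal(rg_values(spectral_index(o2, "MSAVI"))[1, 1], msavi)

  o3 <- obs_of(nir = 0, red = 0, green = 0)
  expect_equal(rg_values(spectral_index(o3, "MSAVI"))[1, 1], 0)
  expect_true(is.na(rg_values(spectral_index(o3, "NDVI"))[1, 1]))

  # bounded on positive reflectances
  set.seed(8)
  o4 <- obs_of(nir = matrix(runif(9, 0.01, 1), 3),
               red = matrix(runif(9, 0.01, 1), 3),
               green = matrix(runif(9, 0.01, 1), 3),
               swir1 = matrix(runif(9, 0.01, 1), 3))
  for (k in c("NDVI", "NDMI", "NDWI")) {
    v <- rg_values(spectral_index(o4, k))
    expect_true(all(v >= -1 & v <= 1))
  }
  expect_true(all(rg_values(spectral_index(o4, "MSAVI")) <= 1))
})

test_that("dry-season compositing uses hemisphere windows and the sample CV", {
  items <- items_of(list("2015-08-01", matrix(0.2, 2, 2)),
                    list("2016-08-01", matrix(0.3, 2, 2)),
                    list("2017-08-01", matrix(0.4, 2, 2)))
  st <- dry_season_stats(items, 2015:2017)
  expect_equal(rg_values(st$mean)[1, 1], 0.3)
  expect_equal(rg_values(st$cv)[1, 1], sd(c(0.2, 0.3, 0.4)) / 0.3)

  # identical annual values: zero CV
  same <- items_of(list("2015-08-01", matrix(0.3, 2, 2)),
                   list("2016-08-01", matrix(0.3, 2, 2)))
  expect_equal(rg_values(dry_season_stats(same, 2015:2016)$cv)[1, 1], 0)

  # an August scene at southern latitudes is outside the dry window
  s_items <- items_of(list("2015-08-15", matrix(9, 2, 2)),
                      list("2015-02-15", matrix(0.5, 2, 2)),
                      list("2016-02-15", matrix(0.7, 2, 2)),
                      origin_lat = -20)
  st_s <- dry_season_stats(s_items, 2015:2016)
  expect_equal(rg_values(st_s$mean)[1, 1], 0.6)

  # order invariance within windows
  sh <- dry_season_stats(rev(items), 2015:2017)
  expect_equal(rg_values(sh$mean), rg_values(st$mean))
  expect_equal(rg_values(sh$cv), rg_values(st$cv))
})

test_that("ETaP averages annual ratios and skips zero-precipitation years", {
  mk_months <- function(year, tval, pval) {
    out_t <- list(); out_p <- list()
    for (m in 1:12) {
      key <- sprintf("%d-%02d", year, m)
      out_t[[key]] <- grid_of(matrix(tval / 12, 2, 2))
      out_p[[key]] <- grid_of(matrix(pval / 12, 2, 2))
    }
    list(t = out_t, p = out_p)
  }
  a <- mk_months(2015, 500, 400); b <- mk_months(2016, 500, 400)
  etap <- compute_etap(c(a$t, b$t), c(a$p, b$p), 2015:2016)
  expect_equal(rg_values(etap)[1, 1], 1.25)

  # mean of annual ratios, not ratio of pooled sums
  c1 <- mk_months(2015, 100, 200); c2 <- mk_months(2016, 300, 200)
  etap2 <- compute_etap(c(c1$t, c2$t), c(c1$p, c2$p), 2015:2016)
  expect_equal(rg_values(etap2)[1, 1], 1.0)

  # zero-precip year excluded from the pixel's average
  z <- mk_months(2015, 100, 0); d <- mk_months(2016, 300, 200)
  etap3 <- compute_etap(c(z$t, d$t), c(z$p, d$p), 2015:2016)
  expect_equal(rg_values(etap3)[1, 1], 1.5)

  expect_error(compute_etap(a$t, a$p, 2015:2016), "mismatched calendars")
})

test_that("CTI ranks valleys above ridges and stays finite on flats", {
  # uniform inclined plane: constant along contour lines (rows)
  nr <- 7; nc <- 7
  plane <- grid_of(outer(seq_len(nr), seq_len(nc), function(i, j) 100 - 2 * i),
                   origin_lat = 0.001)
  cti_p <- rg_values(compute_cti(plane))
  inner <- cti_p[3:5, 3:5]
  for (i in 1:3) expect_lt(diff(range(inner[i, ])), 1e-9)

  # V-shaped valley: center column collects flow everywhere
  v <- outer(seq_len(7), seq_len(7), function(i, j) abs(j - 4) * 5 - 0.1 * i)
  cti_v <- rg_values(compute_cti(grid_of(v, origin_lat = 0.001)))
  for (i in 2:6) {
    expect_gt(cti_v[i, 4], cti_v[i, 2])
    expect_gt(cti_v[i, 4], cti_v[i, 6])
  }

  flat <- grid_of(matrix(50, 5, 5), origin_lat = 0.001)
  expect_true(all(is.finite(rg_values(compute_cti(flat)))))
  expect_error(compute_cti(grid_of(matrix(1, 2, 2))), "3x3")
})

test_that("LST spatial anomaly is zero on constant fields and hand-checkable on spikes", {
  years <- 2016
  const_items <- items_of(list("2016-08-01", matrix(21.5, 9, 9)))
  water0 <- grid_of(matrix(0, 9, 9), origin_lat = 35)
  a0 <- rg_values(compute_lst_anomaly(const_items, water0, years,
                                      scales_px = c(3, 5)))
  expect_equal(max(abs(a0)), 0, tolerance = 1e-12)

  # one +3 degC pixel: anomaly = mean over windows of (3 - 3/n_w)
  v <- matrix(20, 9, 9); v[5, 5] <- 23
  spike <- items_of(list("2016-08-01", v))
  a <- rg_values(compute_lst_anomaly(spike, water0, years, scales_px = c(3, 5)))
  expect_equal(a[5, 5], mean(c(3 - 3 / 9, 3 - 3 / 25)))
  expect_lt(a[5, 4], 0)

  # water pixels leave the window means and the output
  w <- matrix(0, 9, 9); w[5, 5] <- 1
  aw <- rg_values(compute_lst_anomaly(spike, grid_of(w, origin_lat = 35),
                                      years, scales_px = c(3, 5)))
  expect_true(is.na(aw[5, 5]))
  expect_equal(max(abs(aw), na.rm = TRUE), 0, tolerance = 1e-12)

  expect_error(compute_lst_anomaly(spike, water0, years, scales_px = c(0)),
               "window")
})

test_that("LST anomaly has near-zero spatial mean over a large noise field", {
  set.seed(21)
  v <- matrix(30 + rnorm(300 * 300), 300, 300)
  items <- items_of(list("2016-08-01", v))
  water <- grid_of(matrix(0, 300, 300), origin_lat = 35)
  a <- rg_values(compute_lst_anomaly(items, water, 2016))
  expect_lt(abs(mean(a)), 0.05)
})

test_that("stack assembly enforces exactly the 11 canonical layers", {
  full <- stack_of()
  expect_length(full$layers, 11)
  expect_identical(names(full$layers), predictor_names())

  eleven <- lapply(predictor_names(), function(nm) grid_of(matrix(0, 2, 2)))
  names(eleven) <- predictor_names()
  expect_error(assemble_predictors(eleven[-3]), "ndmi_mean")
  dup <- eleven
  names(dup)[2] <- "ndvi_mean"
  expect_error(assemble_predictors(dup), "duplicate")
})

test_that("GDE pixels separate from the matrix on ETaP and LST anomaly", {
  b <- generate_scene(scenario_config(n_rows = 80, n_cols = 80, n_years = 2,
                                      obs_per_season = 2, seed = 14,
                                      gde_fraction = 0.15))
  stack <- compute_predictor_stack(b)
  truth <- b$truth$values == 1
  etap <- rg_values(stack$layers$etap)
  expect_gt(mean(etap[truth], na.rm = TRUE), 1)
  expect_lt(mean(etap[!truth], na.rm = TRUE), 1)
  anom <- rg_values(stack$layers$lst_anom)
  expect_lt(mean(anom[truth], na.rm = TRUE), 0)
  expect_gt(mean(anom[!truth], na.rm = TRUE), 0)
})
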