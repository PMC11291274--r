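test_that("species consensus rules fire in order and reject conflicts", {
  tbl <- data.frame(
    species = c(rep("sp_a", 4), rep("sp_b", 3), rep("sp_c", 3)),
    region = c("AZ", "CA", "NV", "OR", "AZ", "CA", "NV", "AZ", "CA", "NV"),
    flag = c("phreatophyte", "phreatophyte", "not_phreatophyte", "not_phreatophyte",
             "not_phreatophyte", "not_phreatophyte", "not_phreatophyte",
             "phreatophyte", "not_phreatophyte", "not_phreatophyte"),
    stringsAsFactors = FALSE)
  out <- consensus_labels(tbl)
  expect_equal(out$label[out$species == "sp_a"], "GDE")       # 2 yes, 2 no
  expect_equal(out$label[out$species == "sp_b"], "NONGDE")    # 0 yes, 3 no
  expect_false("sp_c" %in% out$species)                       # 1 yes, 2 no
  expect_true("sp_c" %in% attr(out, "excluded_species"))

  dup <- rbind(tbl, data.frame(species = "sp_a", region = "AZ",
                               flag = "not_phreatophyte"))
  expect_error(consensus_labels(dup), "conflicting")
})

test_that("stratified 80/20 split partitions each class deterministically", {
  pts <- data.frame(lon = runif(200), lat = runif(200),
                    label = rep(c("GDE", "NONGDE"), each = 100))
  sp <- split_train_test(pts, 0.8, seed = 5)
  expect_equal(as.vector(table(sp$train$label)), c(80, 80))
  expect_equal(as.vector(table(sp$test$label)), c(20, 20))
  key <- function(d) paste(d$lon, d$lat)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_setequal(c(key(sp$train), key(sp$test)), key(pts))
  sp2 <- split_train_test(pts, 0.8, seed = 5)
  expect_identical(sp$train, sp2$train)
  expect_error(split_train_test(data.frame(label = c("GDE", "NONGDE", "NONGDE"),
                                           lon = 1:3, lat = 1:3)),
               "at least 2")
})

test_that("the forest honours its configuration and separates easy classes", {
  d <- separable_points(n_per_class = 60, seed = 2)
  model <- train_rf(d$points, d$stack, rf_config(seed = 3))
  expect_equal(model$rf$ntree, 40)
  expect_equal(sum(model$feature_importance), 1)
  # nearest-centroid oracle achieves zero error on this geometry
  x <- extract_predictors(d$points, d$stack)
  mu_g <- colMeans(x[d$points$label == "GDE", ])
  mu_n <- colMeans(x[d$points$label == "NONGDE", ])
  pred <- apply(x, 1, function(r)
    if (sum((r - mu_g)^2) < sum((r - mu_n)^2)) "GDE" else "NONGDE")
  expect_equal(mean(pred != d$points$label), 0)
  expect_lte(model$oob_error, 0.05)

  one_class <- d$points[d$points$label == "GDE", ]
  expect_error(train_rf(one_class, d$stack), "one class")

  # degenerate stopping: a huge leaf population halts growth at the root
  # split (the backend always splits a mixed-class root once)
  lone <- train_rf(d$points, d$stack,
                   rf_config(n_trees = 1, min_leaf = 1000, seed = 1))
  expect_lte(nrow(randomForest::getTree(lone$rf, 1)), 3)
})

test_that("probability prediction equals the per-tree vote-counting oracle", {
  d <- separable_points(n_per_class = 40, seed = 4)
  model <- train_rf(d$points, d$stack, rf_config(n_trees = 7, seed = 5))
  pts5 <- d$points[c(1, 11, 41, 55, 77), ]
  p <- predict_point_probability(model, pts5, d$stack)
  x <- as.data.frame(extract_predictors(pts5, d$stack))
  expect_equal(p, vote_fraction_oracle(model, x))
})

test_that("probability maps honour the extent and the layer order contract", {
  d <- separable_points(n_per_class = 40, seed = 6)
  model <- train_rf(d$points, d$stack, rf_config(seed = 6))
  g <- d$stack$layers[[1]]
  ext <- matrix(1, nrow(g$values), ncol(g$values)); ext[1, 1] <- 0
  prob <- predict_probability(model, d$stack, rg_like(g, ext))
  pv <- rg_values(prob)
  expect_true(is.na(pv[1, 1]))
  expect_true(all(pv[-1] >= 0 & pv[-1] <= 1, na.rm = TRUE))

  shuffled <- structure(list(layers = rev(d$stack$layers)),
                        class = "predictor_stack")
  expect_error(predict_probability(model, shuffled, rg_like(g, ext)),
               "layer-order mismatch")
})

test_that("dynamic thresholding picks the smallest accuracy-maximizing cut", {
  val <- data.frame(lon = 0, lat = 0,
                    label = rep(c("GDE", "NONGDE"), each = 10))
  scores <- rep(c(0.9, 0.1), each = 10)
  expect_equal(dynamic_threshold(scores, val), 0.11)
  expect_error(dynamic_threshold(scores, transform(val, label = "GDE")),
               "both classes")

  # oracle equivalence: brute force over every distinct score
  set.seed(9)
  sc <- round(runif(80), 3)
  lab <- ifelse(runif(80) < plogis(6 * (sc - 0.4)), "GDE", "NONGDE")
  if (length(unique(lab)) == 2) {
    v2 <- data.frame(lon = 0, lat = 0, label = lab)
    t_star <- dynamic_threshold(sc, v2)
    acc_at <- function(t) mean(ifelse(sc >= t, "GDE", "NONGDE") == lab)
    best <- max(vapply(c(0, sort(unique(sc)), 1), acc_at, 0))
    expect_equal(acc_at(t_star), best)
  }
})

test_that("binarization uses the inclusive 1/2 coding and is monotone", {
  p <- grid_of(matrix(c(0.5, 0.49, NA, 1), 2, 2))
  m <- binarize(p, 0.5)
  expect_equal(m$binary$values[1, 1], 1)   # exactly 0.50 -> GDE
  expect_equal(rg_values(m$binary)[2, 1], 2)
  expect_true(is.na(rg_values(m$binary)[1, 2]))
  expect_equal(m$threshold, 0.5)

  all_gde <- binarize(p, 0)
  expect_true(all(rg_values(all_gde$binary) == 1, na.rm = TRUE))
  lo <- rg_values(binarize(p, 0.3)$binary) == 1
  hi <- rg_values(binarize(p, 0.7)$binary) == 1
  expect_true(all(lo >= hi, na.rm = TRUE))
  expect_error(binarize(p, 1.2), "\\[0, 1\\]")
})

test_that("confusion metrics match the 2x2 table arithmetic", {
  r <- confusion_metrics(c("GDE", "NONGDE"), c("GDE", "NONGDE"))
  expect_equal(c(r$accuracy, r$precision, r$recall), c(1, 1, 1))

  pred <- c(rep("GDE", 10), rep("NONGDE", 10))
  truth <- c(rep("GDE", 8), rep("NONGDE", 2), "GDE", rep("NONGDE", 9))
  r2 <- confusion_metrics(pred, truth)
  expect_equal(c(r2$tp, r2$fp, r2$fn, r2$tn), c(8, 2, 1, 9))
  expect_equal(r2$accuracy, 0.85)
  expect_equal(r2$precision, 0.80)
  expect_equal(r2$recall, 8 / 9)

  r3 <- confusion_metrics(rep("NONGDE", 4), c("GDE", "GDE", "NONGDE", "NONGDE"))
  expect_true(is.na(r3$precision))
  expect_equal(r3$recall, 0)
  expect_error(confusion_metrics("GDE", c("GDE", "GDE")), "equal length")
})

test_that("overlap index is calibrated at its boundary cases", {
  set.seed(10)
  x <- rnorm(500)
  expect_equal(overlap_index(x, x), 1)
  expect_equal(overlap_index(runif(200, 0, 1), runif(200, 5, 6)), 0)
  expect_equal(overlap_index(rep(3, 20), rep(3, 30)), 1)
  expect_error(overlap_index(rnorm(5), rnorm(100)), "at least 10")
  expect_equal(overlap_index(x, rnorm(500, 0.2)),
               overlap_index(rnorm(500, 0.2), x), tolerance = 0.2)
})

test_that("grid search is exhaustive with the documented tie-breaks", {
  d <- separable_points(n_per_class = 50, seed = 11)
  single <- tune_hyperparameters(d$points, d$stack,
                                 list(n_trees = 25, vars_per_split = 3), seed = 2)
  expect_equal(single$n_trees, 25L)
  expect_equal(single$vars_per_split, 3L)

  best <- tune_hyperparameters(d$points, d$stack,
                               list(n_trees = c(10, 40)), seed = 2)
  expect_equal(best$n_trees, 10L)   # both perfect on separable data
  best2 <- tune_hyperparameters(d$points, d$stack,
                                list(n_trees = c(10, 40)), seed = 2)
  expect_identical(best, best2)
  expect_error(tune_hyperparameters(d$points, d$stack,
                                    list(n_trees = numeric(0))), "empty")
})

test_that("importance ranking highlights the groundwater-subsidy predictors", {
  ranks <- sapply(1:5, function(k) {
    b <- generate_scene(scenario_config(n_rows = 100, n_cols = 100, n_years = 2,
                                        obs_per_season = 2, seed = 400 + k,
                                        gde_fraction = 0.15))
    stack <- compute_predictor_stack(b)
    pts <- sample_points(b, 400, 400, 80, seed = k)
    model <- train_rf(pts, stack, rf_config(seed = k))
    rank(-model$feature_importance)
  })
  rownames(ranks) <- predictor_names()
  # the transpiration:precipitation ratio is a dominant signal
  expect_gte(mean(ranks["etap", ] <= 3), 0.8)
  # the LST anomaly carries real signal: ahead of the interannual-CV layers
  # and topography in most runs
  weak <- c("ndvi_cv", "ndmi_cv", "ndwi_cv", "msavi_cv", "cti")
  expect_gte(mean(apply(ranks, 2, function(r)
    r["lst_anom"] < min(r[weak]))), 0.8)
})

test_that("regional cross-validation scores only the held-out region", {
  d <- separable_points(n_per_class = 60, seed = 12)
  rep_b <- regional_cv(d$points, d$stack, "B", rf_config(seed = 1))
  n_b <- sum(d$points$region == "B")
  expect_equal(rep_b$tp + rep_b$fp + rep_b$fn + rep_b$tn, n_b)
  expect_equal(rep_b$context, "B")
  expect_error(regional_cv(d$points, d$stack, "Z"), "empty holdout")
})
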