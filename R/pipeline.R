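#' Run the full desk-scale GDE mapping analysis on a synthetic scene
#'
#' End-to-end convenience wrapper: generates (or takes) a scene, builds
#' the analysis extent, computes the 11-predictor stack, samples labelled
#' points, splits them 80/20, trains the random-forest classifier,
#' predicts the probability layer over the extent, picks the dynamic
#' threshold on the held-out points, binarizes, and scores both the
#' held-out points and pixelwise agreement with the scene's truth mask.
#'
#' @param config a [scenario_config()]; ignored when `bundle` is given.
#' @param bundle optionally, a pre-generated `scene_bundle`.
#' @param n_gde,n_nongde,n_barren training-point stratum sizes.
#' @param rf an [rf_config()]; its seed defaults to the scenario seed.
#' @param threshold fixed probability threshold; `NULL` (default) selects
#'   it dynamically on the held-out points.
#' @return List with the scene, extent, stack, sampled points, model,
#'   probability map (`gde_map`), held-out `validation_report`, chosen
#'   threshold, pixelwise `truth_agreement`, mapped `gde_area_km2` and the
#'   GDE fraction of the analysed extent.
#' @export
run_gde_analysis <- function(config = scenario_config(), bundle = NULL,
                             n_gde = 1000, n_nongde = 800, n_barren = 200,
                             rf = NULL, threshold = NULL) {
  if (is.null(bundle)) bundle <- generate_scene(config)
  cfg <- bundle$config
  if (is.null(rf)) rf <- rf_config(seed = cfg$seed)
  masks <- .bundle_extent(bundle)
  stack <- compute_predictor_stack(bundle)
  points <- sample_points(bundle, n_gde, n_nongde, n_barren,
                          seed = .sub_seed(cfg$seed, 8))
  sp <- split_train_test(points, 0.8, seed = .sub_seed(cfg$seed, 9))
  model <- train_rf(sp$train, stack, rf)
  prob <- predict_probability(model, stack, masks$extent)
  scores <- predict_point_probability(model, sp$test, stack)
  if (is.null(threshold)) threshold <- dynamic_threshold(scores, sp$test)
  map <- binarize(prob, threshold)
  keep <- !is.na(scores)
  report <- confusion_metrics(
    ifelse(scores[keep] >= threshold, "GDE", "NONGDE"),
    sp$test$label[keep], threshold = threshold, context = "held-out 20%")

  b <- rg_values(map$binary)
  tr <- bundle$truth$values
  scored <- !is.na(b)
  agreement <- mean((b[scored] == 1) == (tr[scored] == 1))
  a <- cell_area_grid(map$binary)
  gde_area <- sum(a[scored & b == 1])

  list(bundle = bundle, masks = masks, stack = stack, points = points,
       split = sp, model = model, map = map, report = report,
       threshold = threshold, truth_agreement = agreement,
       gde_area_km2 = gde_area,
       gde_fraction_of_extent = gde_area / masks$analysed_area_km2)
}
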