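#' Random-forest configuration
#'
#' Defaults are the tuned hyperparameters used for the global dryland GDE
#' classifier: 40 trees, five candidate variables per split, minimum leaf
#' population of two, bag fraction 0.7 and at most 3,010 nodes per tree.
#' The node cap counts all nodes of a binary tree; the underlying
#' implementation controls growth by terminal-node count, so the cap maps
#' to `ceiling(max_nodes / 2)` leaves.
#'
#' @param n_trees number of trees (>= 1).
#' @param vars_per_split candidate predictors per node (1..11).
#' @param min_leaf minimum leaf population.
#' @param bag_fraction bootstrap fraction per tree (sampled with
#'   replacement), in (0, 1].
#' @param max_nodes per-tree cap on total node count.
#' @param seed RNG seed for training.
#' @export
rf_config <- function(n_trees = 40, vars_per_split = 5, min_leaf = 2,
                      bag_fraction = 0.7, max_nodes = 3010, seed = 1) {
  stopifnot(n_trees >= 1, vars_per_split >= 1, vars_per_split <= 11,
            min_leaf >= 1, bag_fraction > 0, bag_fraction <= 1, max_nodes >= 3)
  structure(list(n_trees = as.integer(n_trees),
                 vars_per_split = as.integer(vars_per_split),
                 min_leaf = as.integer(min_leaf),
                 bag_fraction = bag_fraction,
                 max_nodes = as.integer(max_nodes),
                 seed = as.integer(seed)), class = "rf_config")
}

#' Consensus labelling of reference species
#'
#' Applies the multi-region consensus rule used to turn per-region
#' phreatophyte determinations into training labels: a species is labelled
#' `GDE` if two or more regions flag it as a phreatophyte; otherwise it is
#' labelled `NONGDE` if three or more regions flag it as not a
#' phreatophyte; otherwise it is left unlabelled and excluded. The GDE
#' rule is checked first when both fire.
#'
#' @param species_flags data frame with columns `species`, `region`,
#'   `flag` (`"phreatophyte"` or `"not_phreatophyte"`); one row per
#'   (species, region).
#' @return Data frame of labelled species (`species`, `label`); unlabelled
#'   species are in the `"excluded_species"` attribute.
#' @export
consensus_labels <- function(species_flags) {
  stopifnot(all(c("species", "region", "flag") %in% names(species_flags)))
  bad <- setdiff(unique(species_flags$flag), c("phreatophyte", "not_phreatophyte"))
  if (length(bad)) stop("unknown flag value(s): ", paste(bad, collapse = ", "))
  key <- paste(species_flags$species, species_flags$region, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- species_flags[key %in% key[duplicated(key)], ]
    conflicting <- any(tapply(dups$flag, paste(dups$species, dups$region),
                              function(f) length(unique(f)) > 1))
    stop(if (conflicting) "conflicting duplicate rows for (species, region)"
         else "duplicate rows for (species, region)")
  }
  n_ph <- tapply(species_flags$flag == "phreatophyte", species_flags$species, sum)
  n_not <- tapply(species_flags$flag == "not_phreatophyte", species_flags$species, sum)
  sp <- names(n_ph)
  label <- ifelse(n_ph >= 2, "GDE", ifelse(n_not >= 3, "NONGDE", NA))
  out <- data.frame(species = sp[!is.na(label)], label = label[!is.na(label)],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded_species") <- sp[is.na(label)]
  out
}

#' Stratified train/test split
#'
#' Splits a labelled point table 80/20 (by default) within each class,
#' deterministically for a given seed. Train and test are disjoint and
#' their union is the input.
#'
#' @param points point table with a `label` column in {GDE, NONGDE}.
#' @param train_fraction fraction per class assigned to training.
#' @param seed RNG seed.
#' @return `list(train = , test = )`.
#' @export
split_train_test <- function(points, train_fraction = 0.8, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  tab <- table(points$label)
  if (any(tab < 2)) stop("each class needs at least 2 points to split")
  set.seed(seed)
  idx_train <- integer(0)
  for (cl in names(tab)) {
    idx <- which(points$label == cl)
    n_tr <- round(train_fraction * length(idx))
    idx_train <- c(idx_train, sample(idx, n_tr))
  }
  list(train = points[sort(idx_train), , drop = FALSE],
       test = points[setdiff(seq_len(nrow(points)), idx_train), , drop = FALSE])
}

#' Extract predictor values at point locations
#'
#' @param points point table (`lon`, `lat`).
#' @param stack a `predictor_stack`.
#' @return Numeric matrix, one column per predictor, `NA` where a point
#'   falls outside the grid or on a nodata pixel.
#' @export
extract_predictors <- function(points, stack) {
  g <- stack$layers[[1]]
  nr <- nrow(g$values); nc <- ncol(g$values)
  row <- floor((g$origin_lat - points$lat) / g$cell_size) + 1
  col <- floor((points$lon - g$origin_lon) / g$cell_size) + 1
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  out <- matrix(NA_real_, nrow(points), length(stack$layers),
                dimnames = list(NULL, names(stack$layers)))
  idx <- cbind(row[ok], col[ok])
  for (j in seq_along(stack$layers))
    out[ok, j] <- rg_values(stack$layers[[j]])[idx]
  out
}

#' Train the GDE random-forest classifier
#'
#' Bagged ensemble of classification trees over the 11 predictors:
#' each tree is grown on a bootstrap draw (with replacement) of
#' `bag_fraction` of the training points, considering `vars_per_split`
#' candidate predictors per node (Gini impurity), with growth stopped by
#' the minimum leaf population and node cap. Points with any nodata
#' predictor are dropped with a message. The out-of-bag error and
#' normalized feature importances are recorded.
#'
#' @param train labelled point table.
#' @param stack a `predictor_stack`.
#' @param config an [rf_config()].
#' @return A `gde_rf_model`.
#' @export
train_rf <- function(train, stack, config = rf_config()) {
  x <- extract_predictors(train, stack)
  y <- train$label
  keep <- stats::complete.cases(x)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " training point(s) dropped for nodata predictors")
  x <- x[keep, , drop = FALSE]
  y <- factor(y[keep], levels = c("GDE", "NONGDE"))
  if (length(unique(y)) < 2) stop("training points contain only one class")
  set.seed(config$seed)
  n <- nrow(x)
  bag <- max(2L, ceiling(config$bag_fraction * n))
  rf <- randomForest::randomForest(
    x = as.data.frame(x), y = y,
    ntree = config$n_trees,
    mtry = min(config$vars_per_split, ncol(x)),
    nodesize = config$min_leaf,
    maxnodes = min(ceiling(config$max_nodes / 2), bag),
    replace = TRUE,
    sampsize = bag,
    importance = TRUE)
  imp <- randomForest::importance(rf, type = 2)[, 1]
  structure(list(rf = rf,
                 layer_names = colnames(x),
                 config = config,
                 oob_error = unname(rf$err.rate[config$n_trees, "OOB"]),
                 feature_importance = imp / sum(imp),
                 n_dropped = n_dropped),
            class = "gde_rf_model")
}

#' @export
print.gde_rf_model <- function(x, ...) {
  cat(sprintf("<gde_rf_model> %d trees, OOB error %.3f\n",
              x$config$n_trees, x$oob_error))
  cat("  top importances:",
      paste(names(sort(x$feature_importance, decreasing = TRUE))[1:3],
            collapse = ", "), "\n")
  invisible(x)
}

#' GDE probability prediction over the analysis extent
#'
#' Per extent pixel, the GDE probability is the fraction of trees voting
#' GDE (the ensemble's probabilistic output mode). Pixels outside the
#' extent, and extent pixels with any nodata predictor, are nodata.
#'
#' @param model a `gde_rf_model`.
#' @param stack a `predictor_stack` whose layers match the training layout.
#' @param extent binary `raster_grid` (1 = analysed).
#' @return Probability `raster_grid` in \[0, 1\].
#' @export
predict_probability <- function(model, stack, extent) {
  if (!identical(names(stack$layers), model$layer_names))
    stop("layer-order mismatch between stack and trained model")
  g <- stack$layers[[1]]
  .assert_registered(g, extent, what = "stack/extent grids")
  ev <- rg_values(extent)
  idx <- which(!is.na(ev) & ev == 1)
  out <- matrix(NA_real_, nrow(g$values), ncol(g$values))
  if (length(idx)) {
    x <- vapply(stack$layers, function(l) rg_values(l)[idx],
                numeric(length(idx)))
    if (length(idx) == 1) x <- matrix(x, 1, dimnames = list(NULL, names(stack$layers)))
    ok <- stats::complete.cases(x)
    if (any(ok)) {
      p <- stats::predict(model$rf, newdata = as.data.frame(x[ok, , drop = FALSE]),
                          type = "prob")[, "GDE"]
      res <- rep(NA_real_, length(idx))
      res[ok] <- p
      out[idx] <- res
    }
  }
  rg_like(g, out, "gde_probability")
}

#' GDE probability at point locations
#'
#' @inheritParams predict_probability
#' @param points point table.
#' @return Numeric vector of GDE vote fractions (`NA` where predictors are
#'   unavailable).
#' @export
predict_point_probability <- function(model, points, stack) {
  if (!identical(names(stack$layers), model$layer_names))
    stop("layer-order mismatch between stack and trained model")
  x <- extract_predictors(points, stack)
  ok <- stats::complete.cases(x)
  p <- rep(NA_real_, nrow(x))
  if (any(ok))
    p[ok] <- stats::predict(model$rf, newdata = as.data.frame(x[ok, , drop = FALSE]),
                            type = "prob")[, "GDE"]
  p
}

#' Dynamic probability threshold
#'
#' Sweeps thresholds 0.00, 0.01, ..., 1.00, classifying a point as GDE when
#' its score is greater than or equal to the threshold, and returns the
#' threshold maximizing accuracy against the validation labels (smallest
#' threshold on ties). This is how the "hard" binary map is derived from
#' the "soft" probability layer.
#'
#' @param scores probability `raster_grid` (sampled at the validation
#'   points) or a numeric score vector aligned with `validation`.
#' @param validation labelled point table with both classes present.
#' @return The selected threshold.
#' @export
dynamic_threshold <- function(scores, validation) {
  if (inherits(scores, "raster_grid")) {
    stack1 <- structure(list(layers = list(p = scores)), class = "predictor_stack")
    scores <- extract_predictors(validation, stack1)[, 1]
  }
  keep <- !is.na(scores) & !is.na(validation$label)
  scores <- scores[keep]
  labels <- validation$label[keep]
  if (length(unique(labels)) < 2)
    stop("validation set must contain both classes")
  thresholds <- seq(0, 1, by = 0.01)
  acc <- vapply(thresholds, function(t)
    mean(ifelse(scores >= t, "GDE", "NONGDE") == labels), 0)
  thresholds[which.max(acc)]
}

#' Binarize a probability layer into a GDE map
#'
#' Probability >= threshold becomes class 1 (GDE), below becomes class 2
#' (non-GDE); nodata is preserved. The default 50% threshold maps the
#' stated likelihood cut inclusively (a pixel at exactly 0.5 is GDE).
#'
#' @param probability probability `raster_grid` in \[0, 1\].
#' @param threshold likelihood cut in \[0, 1\].
#' @return A `gde_map`: `probability`, `binary` (1/2 coding) and
#'   `threshold`.
#' @export
binarize <- function(probability, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  p <- rg_values(probability)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("probability values must lie in [0, 1]")
  b <- ifelse(is.na(p), NA_real_, ifelse(p >= threshold, 1, 2))
  structure(list(probability = probability,
                 binary = rg_like(probability, b, "gde_class"),
                 threshold = threshold), class = "gde_map")
}

#' @export
print.gde_map <- function(x, ...) {
  b <- rg_values(x$binary)
  cat(sprintf("<gde_map> threshold %.2f: %d GDE / %d non-GDE / %d nodata pixels\n",
              x$threshold, sum(b == 1, na.rm = TRUE), sum(b == 2, na.rm = TRUE),
              sum(is.na(b))))
  invisible(x)
}

#' Confusion-matrix validation metrics
#'
#' GDE is the positive class. Accuracy = (tp + tn) / total; precision =
#' tp / (tp + fp), the share of predicted GDEs that are actual GDEs;
#' recall = tp / (tp + fn), the share of actual GDEs predicted correctly.
#' Ratios with a zero denominator are reported as `NA`.
#'
#' @param predicted,truth label vectors in {GDE, NONGDE}, equal length.
#' @param threshold,context optional metadata carried into the report.
#' @return A `validation_report`.
#' @export
confusion_metrics <- function(predicted, truth, threshold = NA_real_,
                              context = "") {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  predicted <- as.character(predicted); truth <- as.character(truth)
  bad <- setdiff(unique(c(predicted, truth)), c("GDE", "NONGDE"))
  if (length(bad)) stop("labels outside {GDE, NONGDE}: ", paste(bad, collapse = ", "))
  tp <- sum(predicted == "GDE" & truth == "GDE")
  fp <- sum(predicted == "GDE" & truth == "NONGDE")
  fn <- sum(predicted == "NONGDE" & truth == "GDE")
  tn <- sum(predicted == "NONGDE" & truth == "NONGDE")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = ratio(tp + tn, tp + fp + fn + tn),
                 precision = ratio(tp, tp + fp),
                 recall = ratio(tp, tp + fn),
                 threshold = threshold, context = context),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report%s> acc %.3f, precision %s, recall %s (tp %d fp %d fn %d tn %d)\n",
              if (nzchar(x$context)) paste0(" ", x$context) else "",
              x$accuracy, format(round(x$precision, 3)),
              format(round(x$recall, 3)), x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Regional cross-validation
#'
#' Trains on all points outside `holdout_region` and evaluates on the
#' points inside it — the protocol for judging how the classifier
#' extrapolates into regions without training data.
#'
#' @param points labelled point table with a `region` column.
#' @param stack a `predictor_stack`.
#' @param holdout_region region tag to hold out.
#' @param config an [rf_config()].
#' @param threshold probability threshold for classification.
#' @return A `validation_report` tagged with the region.
#' @export
regional_cv <- function(points, stack, holdout_region, config = rf_config(),
                        threshold = 0.5) {
  hold <- points$region == holdout_region
  if (!any(hold)) stop("empty holdout: no points in region ", holdout_region)
  model <- train_rf(points[!hold, , drop = FALSE], stack, config)
  p <- predict_point_probability(model, points[hold, , drop = FALSE], stack)
  keep <- !is.na(p)
  confusion_metrics(ifelse(p[keep] >= threshold, "GDE", "NONGDE"),
                    points$label[hold][keep],
                    threshold = threshold, context = holdout_region)
}

#' Distribution overlap index
#'
#' Estimates the integral of the pointwise minimum of two densities from
#' shared-range histograms with a common Freedman-Diaconis bin width on
#' the pooled sample: 0 means disjoint distributions, 1 identical.
#' Symmetric in its arguments.
#'
#' @param sample_a,sample_b numeric samples (n >= 10 each).
#' @return Overlap estimate in \[0, 1\].
#' @export
overlap_index <- function(sample_a, sample_b) {
  a <- sample_a[!is.na(sample_a)]; b <- sample_b[!is.na(sample_b)]
  if (length(a) < 10 || length(b) < 10)
    stop("each sample needs at least 10 values")
  pooled <- c(a, b)
  rng <- range(pooled)
  if (diff(rng) == 0) return(1)   # zero spread: both samples one value
  h <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
  n_bins <- if (h > 0) max(1L, ceiling(diff(rng) / h))
            else ceiling(log2(length(pooled)) + 1)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- function(x) {
    i <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(i, nbins = n_bins) / length(x)
  }
  sum(pmin(bin(a), bin(b)))
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every configuration in the grid by held-out accuracy on an
#' internal stratified 80/20 split and returns the best, breaking ties
#' towards fewer trees, then fewer variables per split.
#'
#' @param points labelled point table.
#' @param stack a `predictor_stack`.
#' @param grid named list of value vectors for any of `n_trees`,
#'   `vars_per_split`, `min_leaf`, `bag_fraction`, `max_nodes`.
#' @param seed seed for the split and every training run.
#' @return The winning [rf_config()].
#' @export
tune_hyperparameters <- function(points, stack, grid, seed = 1) {
  defaults <- rf_config(seed = seed)
  known <- c("n_trees", "vars_per_split", "min_leaf", "bag_fraction", "max_nodes")
  bad <- setdiff(names(grid), known)
  if (length(bad)) stop("unknown grid dimension(s): ", paste(bad, collapse = ", "))
  for (k in setdiff(known, names(grid))) grid[[k]] <- defaults[[k]]
  cand <- expand.grid(grid[known], KEEP.OUT.ATTRS = FALSE)
  if (nrow(cand) == 0) stop("empty hyperparameter grid")
  sp <- split_train_test(points, 0.8, seed)
  acc <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cfg <- rf_config(cand$n_trees[i], cand$vars_per_split[i], cand$min_leaf[i],
                     cand$bag_fraction[i], cand$max_nodes[i], seed = seed)
    model <- train_rf(sp$train, stack, cfg)
    p <- predict_point_probability(model, sp$test, stack)
    keep <- !is.na(p)
    acc[i] <- mean(ifelse(p[keep] >= 0.5, "GDE", "NONGDE") == sp$test$label[keep])
  }
  ord <- order(-acc, cand$n_trees, cand$vars_per_split)
  best <- cand[ord[1], ]
  rf_config(best$n_trees, best$vars_per_split, best$min_leaf,
            best$bag_fraction, best$max_nodes, seed = seed)
}
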