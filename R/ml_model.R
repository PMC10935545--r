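#' Seeded train/test split of a feature matrix
#'
#' Splits by mother cell (rows), never by frame: rows are shuffled with
#' the given seed and the first `1 - fraction` share becomes training
#' data.
#'
#' @param fm A `feature_matrix` (or any data frame of mothers).
#' @param fraction Test fraction (default 0.2, an 80:20 split).
#' @param seed Integer seed for reproducible membership.
#' @return List with `train` and `test` data frames (attributes
#'   preserved) and the index vectors `train_idx`, `test_idx`.
#' @export
split_train_test <- function(fm, fraction = 0.2, seed = 1L) {
  n <- nrow(fm)
  if (n < 50)
    stop("split_train_test: need at least 50 mothers, got ", n,
         call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  n_test <- max(1L, round(fraction * n))
  test_idx <- sort(idx[seq_len(n_test)])
  train_idx <- sort(idx[-seq_len(n_test)])
  man <- attr(fm, "manifest")
  train <- fm[train_idx, , drop = FALSE]
  test <- fm[test_idx, , drop = FALSE]
  attr(train, "manifest") <- man
  attr(test, "manifest") <- man
  list(train = train, test = test,
       train_idx = train_idx, test_idx = test_idx)
}

#' Prediction accuracy as one minus mean relative error
#'
#' `A = 1 - mean(|pred - obs| / obs)`: 1 for perfect prediction, and
#' unbounded below (negative values possible and reported as-is).
#' Observations must be strictly positive.
#'
#' @param pred,obs Numeric vectors of equal length.
#' @return Scalar accuracy in `(-Inf, 1]`.
#' @export
prediction_accuracy <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (any(obs <= 0))
    stop("prediction_accuracy: observations must be strictly positive",
         call. = FALSE)
  1 - mean(abs(pred - obs) / obs)
}

#' Train the random-forest regressor for response peaks
#'
#' 100 bootstrap-trained regression trees predicting the mother-cell
#' reporter peak (`grxa_peak`) from the feature columns; the forest
#' prediction is the tree mean. Trees are grown effectively
#' unconstrained (the configured depth cap of 3000 exceeds any tree the
#' data can produce) and every feature is considered at each split.
#'
#' @param train Training `feature_matrix`.
#' @param n_trees Number of trees.
#' @param max_depth Depth cap, recorded in the model; tree growth is
#'   limited by terminal-node size, which this cap never binds.
#' @param mtry Features tried per split; default all features.
#' @param seed Integer seed.
#' @param features Feature columns to use; default the full manifest.
#' @return A `randomForest` model with attributes `features` and
#'   `depth_cap`.
#' @export
train_regressor <- function(train, n_trees = 100, max_depth = 3000,
                            mtry = NULL, seed = 1L, features = NULL) {
  if (is.null(features)) features <- feature_columns(train)
  miss <- setdiff(features, names(train))
  if (length(miss))
    stop("train_regressor: matrix lacks feature columns: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  x <- as.matrix(train[, features, drop = FALSE])
  if (anyNA(x))
    stop("train_regressor: missing values in feature columns: ",
         paste(colnames(x)[colSums(is.na(x)) > 0], collapse = ", "),
         call. = FALSE)
  y <- train$grxa_peak
  if (is.null(mtry)) mtry <- length(features)
  set.seed(seed)
  model <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees, mtry = mtry,
    importance = FALSE  # IncNodePurity (impurity decrease) is always kept
  )
  attr(model, "features") <- features
  attr(model, "depth_cap") <- max_depth
  model
}

#' Normalised impurity importances and group shares
#'
#' Mean-decrease-impurity importances normalised to sum to 1, grouped
#' by the manifest's mother/barrier tag, with the cumulative share of
#' the top-k features.
#'
#' @param model A model from [train_regressor()].
#' @param manifest A manifest from [feature_manifest()]; defaults to the
#'   packaged one.
#' @param top_k How many leading features to accumulate (default 2).
#' @return List: `per_feature` (named, sums to 1), `mother_share`,
#'   `barrier_share`, `top_k`, `top_k_share`, `top_features`.
#' @export
model_importances <- function(model, manifest = feature_manifest(),
                              top_k = 2) {
  imp <- randomForest::importance(model, type = 2)[, 1]
  feats <- attr(model, "features")
  if (is.null(feats)) feats <- names(imp)
  if (!all(names(imp) %in% manifest$feature))
    stop("model_importances: model features are not in the manifest",
         call. = FALSE)
  w <- imp / sum(imp)
  grp <- manifest$group[match(names(w), manifest$feature)]
  ord <- order(w, decreasing = TRUE)
  list(
    per_feature = w,
    mother_share = sum(w[grp == "mother"]),
    barrier_share = sum(w[grp == "barrier"]),
    top_k = top_k,
    top_k_share = sum(w[ord[seq_len(min(top_k, length(w)))]]),
    top_features = names(w)[ord[seq_len(min(top_k, length(w)))]]
  )
}

#' Full regression report: fit, predict, accuracy, importances
#'
#' Convenience wrapper running the seeded split, the forest fit, the
#' held-out accuracy metric and the grouped importances in one call.
#'
#' @param fm A `feature_matrix`.
#' @param fraction Test fraction.
#' @param n_trees,max_depth,mtry,seed Passed to [train_regressor()].
#' @param features Optional feature subset (e.g. barrier-only columns).
#' @return List of class `model_report`: `accuracy`, `importances`,
#'   `predicted`, `observed`, `n_train`, `n_test`, `n_features`, `seed`,
#'   `depth_cap`.
#' @export
fit_peak_regressor <- function(fm, fraction = 0.2, n_trees = 100,
                               max_depth = 3000, mtry = NULL, seed = 1L,
                               features = NULL) {
  sp <- split_train_test(fm, fraction = fraction, seed = seed)
  model <- train_regressor(sp$train, n_trees = n_trees,
                           max_depth = max_depth, mtry = mtry,
                           seed = seed + 1L, features = features)
  feats <- attr(model, "features")
  pred <- stats::predict(model,
                         as.matrix(sp$test[, feats, drop = FALSE]))
  obs <- sp$test$grxa_peak
  man <- attr(fm, "manifest")
  if (is.null(man)) man <- feature_manifest()
  rep <- list(
    accuracy = prediction_accuracy(pred, obs),
    importances = model_importances(model, man),
    predicted = unname(pred), observed = obs,
    n_train = nrow(sp$train), n_test = nrow(sp$test),
    n_features = length(feats), seed = seed, depth_cap = max_depth
  )
  class(rep) <- "model_report"
  rep
}

#' Barrier-only regression model
#'
#' Refits the peak regressor using only the 56 features derived from
#' the four barrier-cell series (7 statistics x 4 series x 2 epochs),
#' to test whether the environment alone predicts the mother response.
#'
#' @inheritParams fit_peak_regressor
#' @return A `model_report` (with `n_features` = 56).
#' @export
barrier_only_model <- function(fm, fraction = 0.2, n_trees = 100,
                               seed = 1L) {
  man <- attr(fm, "manifest")
  if (is.null(man)) man <- feature_manifest()
  feats <- man$feature[man$group == "barrier"]
  miss <- setdiff(feats, names(fm))
  if (length(miss))
    stop("barrier_only_model: matrix lacks barrier feature columns",
         call. = FALSE)
  fit_peak_regressor(fm, fraction = fraction, n_trees = n_trees,
                     seed = seed, features = feats)
}

#' Random-forest concentration classifier
#'
#' Treats each external H2O2 concentration as a class and predicts it
#' from the same 126 features by majority vote over 100 trees
#' (sqrt-of-p features per split). Returns the row-normalised confusion
#' matrix on the held-out split.
#'
#' @param fm A `feature_matrix` whose `external_c0` column holds the
#'   class labels.
#' @param fraction Test fraction.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @param min_per_class Minimum mothers required per class.
#' @return List: `confusion` (row-normalised), `counts` (raw),
#'   `accuracy` (overall fraction correct), `classes`.
#' @export
train_classifier <- function(fm, fraction = 0.2, n_trees = 100,
                             seed = 1L, min_per_class = 25) {
  cls <- factor(fm$external_c0)
  if (nlevels(cls) < 2)
    stop("train_classifier: need at least 2 concentration classes",
         call. = FALSE)
  tab <- table(cls)
  if (any(tab < min_per_class))
    stop("train_classifier: classes below the minimum of ",
         min_per_class, " mothers: ",
         paste(names(tab)[tab < min_per_class], collapse = ", "),
         call. = FALSE)
  feats <- feature_columns(fm)
  sp <- split_train_test(fm, fraction = fraction, seed = seed)
  set.seed(seed + 1L)
  model <- randomForest::randomForest(
    x = as.matrix(sp$train[, feats, drop = FALSE]),
    y = factor(sp$train$external_c0, levels = levels(cls)),
    ntree = n_trees, mtry = max(1L, floor(sqrt(length(feats)))))
  pred <- stats::predict(model,
                         as.matrix(sp$test[, feats, drop = FALSE]))
  obs <- factor(sp$test$external_c0, levels = levels(cls))
  counts <- table(observed = obs, predicted = pred)
  confusion <- sweep(counts, 1, pmax(rowSums(counts), 1), "/")
  list(confusion = confusion, counts = counts,
       accuracy = mean(pred == obs), classes = levels(cls))
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "random-forest peak regressor: %d features, %d train / %d test\n",
    x$n_features, x$n_train, x$n_test))
  cat(sprintf("  accuracy A = %.3f\n", x$accuracy))
  cat(sprintf("  barrier share = %.3f, mother share = %.3f\n",
              x$importances$barrier_share, x$importances$mother_share))
  cat(sprintf("  top-%d share = %.3f (%s)\n", x$importances$top_k,
              x$importances$top_k_share,
              paste(x$importances$top_features, collapse = ", ")))
  invisible(x)
}
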