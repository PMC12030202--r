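#' Random-forest hyperparameters for NNI inversion
#'
#' Mirrors the settings used for the NNI inversion: 100 trees, maximum
#' depth 2, minimum samples to split 2, minimum samples per leaf 2.  The
#' depth is translated to the tree-size limit of [randomForest::randomForest]
#' as `maxnodes = 2^max_depth` (terminal nodes of a depth-d binary tree);
#' `min_samples_leaf` maps to `nodesize`.  `min_samples_split = 2` imposes
#' no constraint (any splittable node has >= 2 samples) and is retained
#' for documentation only.  `max_depth = NULL` grows unrestricted trees.
#'
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth (NULL for unrestricted).
#' @param min_samples_split,min_samples_leaf minimum node sizes.
#' @param seed integer seed controlling the forest's randomness.
#' @return list of class `inversion_spec`.
#' @export
inversion_spec <- function(n_trees = 100, max_depth = 2,
                           min_samples_split = 2, min_samples_leaf = 2,
                           seed = 1L) {
  stopifnot(n_trees >= 1, min_samples_split >= 1, min_samples_leaf >= 1)
  if (!is.null(max_depth) && max_depth < 1) stop("'max_depth' must be >= 1")
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 min_samples_split = as.integer(min_samples_split),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 seed = as.integer(seed)),
            class = "inversion_spec")
}

#' Stratified train/test split
#'
#' Randomly assigns records to a training and a testing set (default
#' 70/30), stratified by growth stage so every stage is represented in
#' both sets in the same proportion.  Deterministic for a fixed seed.
#'
#' @param data data.frame of records.
#' @param train_fraction fraction assigned to training.
#' @param seed integer seed.
#' @param stratify_by column name to stratify on (NULL for a pooled
#'   split).
#' @return list with `train` and `test` data.frames (disjoint,
#'   exhaustive).
#' @examples
#' d <- data.frame(stage = rep(c("TR", "JT", "HD", "FL"), each = 20))
#' s <- split_dataset(d, 0.7, seed = 1)
#' nrow(s$train); nrow(s$test)  # 56, 24
#' @export
split_dataset <- function(data, train_fraction = 0.7, seed = 1L,
                          stratify_by = "stage") {
  if (nrow(data) < 10) stop("need at least 10 records to split")
  if (train_fraction <= 0 || train_fraction > 1)
    stop("'train_fraction' must lie in (0, 1]")
  set.seed(as.integer(seed))
  strata <- if (!is.null(stratify_by) && stratify_by %in% names(data))
    as.character(data[[stratify_by]]) else rep("all", nrow(data))
  idx_train <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_tr <- floor(train_fraction * length(idx) + 0.5)
    idx_train <- c(idx_train, sort(sample(idx, n_tr)))
  }
  idx_train <- sort(idx_train)
  if (length(idx_train) == nrow(data))
    warning("empty test set (train_fraction covers every record)")
  list(train = data[idx_train, , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), idx_train), , drop = FALSE])
}

#' Fit the random-forest NNI inversion model
#'
#' Trains a random-forest regression of NNI on a set of selected
#' vegetation indices.  Predictions of a regression forest are averages of
#' training responses, so they always lie within the training NNI range.
#'
#' @param train training data.frame containing `response` and all
#'   `features` columns, with no missing values in the features.
#' @param features character vector of feature (vegetation-index) column
#'   names.
#' @param response response column name (default `"nni"`).
#' @param spec an [inversion_spec()].
#' @return object of class `nni_rf` wrapping the fitted forest, with the
#'   feature list, spec, and training response range.
#' @export
fit_nni_rf <- function(train, features, response = "nni",
                       spec = inversion_spec()) {
  stopifnot(inherits(spec, "inversion_spec"))
  miss <- setdiff(c(features, response), names(train))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- features[vapply(train[features],
                         function(v) any(!is.finite(v)), logical(1))]
  if (length(bad))
    stop("undefined feature values in: ", paste(bad, collapse = ", "))
  x <- train[, features, drop = FALSE]
  y <- train[[response]]
  maxnodes <- if (is.null(spec$max_depth)) NULL else 2L^spec$max_depth
  set.seed(spec$seed)
  fit <- randomForest::randomForest(
    x = x, y = y, ntree = spec$n_trees,
    nodesize = spec$min_samples_leaf, maxnodes = maxnodes)
  structure(list(forest = fit, features = features, response = response,
                 spec = spec, train_range = range(y), n_train = nrow(train)),
            class = "nni_rf")
}

#' @export
print.nni_rf <- function(x, ...) {
  cat(sprintf("Random-forest NNI inversion: %d trees, depth %s, %d features\n",
              x$spec$n_trees,
              if (is.null(x$spec$max_depth)) "unrestricted"
              else as.character(x$spec$max_depth),
              length(x$features)))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  trained on %d records, NNI range [%.3f, %.3f]\n",
              x$n_train, x$train_range[1], x$train_range[2]))
  invisible(x)
}

#' Predict NNI from vegetation indices
#'
#' @param object a fitted `nni_rf` model.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return numeric vector of predicted NNI.
#' @export
predict.nni_rf <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  as.numeric(stats::predict(object$forest,
                            newdata[, object$features, drop = FALSE]))
}

#' Inversion-model evaluation metrics
#'
#' Computes root-mean-square error
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum_i (y_i - \hat y_i)^2}},
#' the coefficient of determination \eqn{R^2 = 1 - SSE/SST}, an accuracy
#' measure defined as one minus the mean relative error
#' \eqn{1 - \frac{1}{n}\sum_i |\hat y_i - y_i| / y_i}, and the
#' through-origin least-squares slope of predicted on measured
#' \eqn{k = \sum_i \hat y_i y_i / \sum_i y_i^2} (a 1:1 fit gives k = 1).
#'
#' @param predicted,measured numeric vectors of equal length.
#' @return list with `r2`, `rmse`, `accuracy`, `k`, `n`.
#' @examples
#' evaluate_inversion(c(1.1, 0.9, 1.1, 0.9), c(1, 1, 1, 1))$rmse  # 0.1
#' @export
evaluate_inversion <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("'predicted' and 'measured' must have the same length")
  err <- predicted - measured
  sst <- sum((measured - mean(measured))^2)
  list(r2 = if (sst > 0) 1 - sum(err^2) / sst else NA_real_,
       rmse = sqrt(mean(err^2)),
       accuracy = 1 - mean(abs(err) / measured),
       k = sum(predicted * measured) / sum(measured^2),
       n = length(measured))
}
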