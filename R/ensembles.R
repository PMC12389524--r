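#' Fit a gradient-boosted decision tree regressor
#'
#' Stagewise boosting under squared-error loss: the initial prediction is
#' `mean(y)`; stage m fits a CART tree to the residuals of the model after
#' stage m-1, and the model is updated as
#' \deqn{f_m(x) = f_{m-1}(x) + \nu \, T_m(x)}
#' with learning rate \eqn{\nu}.
#'
#' @param X descriptor matrix.
#' @param y response vector.
#' @param n_stages number of boosting stages (>= 1).
#' @param learning_rate shrinkage applied to each tree's contribution.
#' @param control a [tree_config()] for the stage trees.
#' @return An object of class `gbdt_model` with `stages` (list of trees),
#'   `learning_rate`, `n_stages`, `initial_prediction` and the per-stage
#'   training SSE trace.
#' @export
fit_gbdt <- function(X, y, n_stages = 100L, learning_rate = 0.1,
                     control = tree_config(max_depth = 3L)) {
  X <- as.matrix(X)
  n_stages <- as.integer(n_stages)
  if (n_stages < 1L) stop("n_stages must be >= 1", call. = FALSE)
  f <- rep(mean(y), length(y))
  stages <- vector("list", n_stages)
  sse_trace <- numeric(n_stages)
  for (m in seq_len(n_stages)) {
    tree <- fit_regression_tree(X, y - f, control)
    stages[[m]] <- tree
    f <- f + learning_rate * predict(tree, X)
    sse_trace[m] <- sum((y - f)^2)
  }
  structure(list(stages = stages, learning_rate = learning_rate,
                 n_stages = n_stages, initial_prediction = mean(y),
                 sse_trace = sse_trace, n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "gbdt_model")
}

#' @export
predict.gbdt_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  f <- rep(object$initial_prediction, nrow(X))
  for (tree in object$stages) {
    f <- f + object$learning_rate * predict(tree, X)
  }
  f
}

#' Fit a random forest regressor
#'
#' Each tree is fit on a bootstrap resample (with replacement, size n) drawn
#' from a seeded generator; predictions are the mean over trees. Feature
#' subsampling, when requested, draws a per-tree random subset of columns
#' (the canonical parameterization of this model family uses all features,
#' which is the default).
#'
#' @param X descriptor matrix.
#' @param y response vector.
#' @param n_trees number of trees (>= 1).
#' @param control a [tree_config()].
#' @param seed integer seed; the same seed reproduces the forest exactly.
#' @param feature_subsample fraction of features drawn per tree, in (0, 1].
#' @param bootstrap set `FALSE` to fit every tree on the full sample
#'   (degenerate forest, useful for testing).
#' @return An object of class `rf_model`.
#' @export
fit_rf <- function(X, y, n_trees = 500L, control = tree_config(),
                   seed = 1L, feature_subsample = 1, bootstrap = TRUE) {
  X <- as.matrix(X)
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  if (feature_subsample <= 0 || feature_subsample > 1) {
    stop("feature_subsample must be in (0, 1]", call. = FALSE)
  }
  n <- length(y)
  p <- ncol(X)
  k <- max(1L, round(feature_subsample * p))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(t) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    feats <- if (k < p) sort(sample.int(p, k)) else seq_len(p)
    tree <- fit_regression_tree(X[idx, feats, drop = FALSE], y[idx], control)
    list(tree = tree, features = feats)
  }))
  structure(list(trees = trees, n_trees = n_trees, tree_config = control,
                 bootstrap_seed = seed, n_features = p,
                 feature_names = colnames(X)),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  preds <- vapply(object$trees, function(t) {
    predict(t$tree, X[, t$features, drop = FALSE])
  }, numeric(nrow(X)))
  rowMeans(matrix(preds, nrow = nrow(X)))
}

# Sum of recorded split gains per (global) feature index for one tree.
tree_gain_by_feature <- function(tree, features, p) {
  out <- numeric(p)
  nodes <- tree$nodes
  internal <- !nodes$is_leaf
  if (any(internal)) {
    local <- nodes$feature[internal]
    gains <- nodes$gain[internal]
    for (i in seq_along(local)) {
      g <- features[local[i]]
      out[g] <- out[g] + gains[i]
    }
  }
  out
}

#' Split-gain feature importance of a tree ensemble
#'
#' The squared importance of a feature in one tree is the sum of the
#' squared-error improvements of the splits made on that feature; ensemble
#' importance averages the per-tree sums over all trees. The ranking is
#' non-increasing with ties broken by column index.
#'
#' @param model a `gbdt_model` or `rf_model`.
#' @return An `importance_report` data.frame with columns `feature`,
#'   `importance`, `share` (normalized to sum to 1 when any split exists),
#'   `rank` and `ratio_to_next` (importance divided by the next-ranked
#'   importance, an aid for gap heuristics).
#' @export
split_gain_importance <- function(model) {
  if (inherits(model, "gbdt_model")) {
    p <- model$n_features
    per_tree <- lapply(model$stages, tree_gain_by_feature,
                       features = seq_len(p), p = p)
  } else if (inherits(model, "rf_model")) {
    p <- model$n_features
    per_tree <- lapply(model$trees, function(t) {
      tree_gain_by_feature(t$tree, t$features, p)
    })
  } else {
    stop("model must be a fitted gbdt_model or rf_model", call. = FALSE)
  }
  importance <- Reduce(`+`, per_tree) / length(per_tree)
  total <- sum(importance)
  share <- if (total > 0) importance / total else rep(0, p)
  ord <- order(-importance, seq_len(p))
  names <- model$feature_names %||% paste0("x", seq_len(p))
  report <- data.frame(feature = names[ord],
                       importance = importance[ord],
                       share = share[ord],
                       rank = seq_len(p),
                       stringsAsFactors = FALSE)
  report$ratio_to_next <- c(report$importance[-p] /
                              pmax(report$importance[-1], .Machine$double.eps),
                            NA_real_)
  class(report) <- c("importance_report", "data.frame")
  report
}

#' Select descriptors by split-gain ranking under a correlation filter
#'
#' Fits a gradient-boosted ensemble on all descriptors, ranks them by
#' split-gain importance, then walks the ranking keeping a descriptor only
#' if its absolute Pearson correlation with every already-kept descriptor is
#' below `corr_threshold`, until `k` are kept or the ranking is exhausted.
#'
#' @param table a [descriptor_table()].
#' @param k number of descriptors to keep (>= 1).
#' @param corr_threshold pairwise |Pearson r| bound (default 0.8).
#' @param n_stages,learning_rate,control configuration of the importance
#'   ensemble.
#' @return A list with `selected` (kept names in rank order), `report` (the
#'   [split_gain_importance()] table) and `warning` (`TRUE` when fewer than
#'   `k` descriptors survive the filter, in which case a warning is also
#'   signalled).
#' @export
select_descriptors <- function(table, k, corr_threshold = 0.8,
                               n_stages = 50L, learning_rate = 0.1,
                               control = tree_config(max_depth = 3L)) {
  stopifnot(inherits(table, "descriptor_table"))
  p <- ncol(table$descriptors)
  if (k < 1L || k > p) {
    stop("k must be between 1 and the descriptor count", call. = FALSE)
  }
  model <- fit_gbdt(table$descriptors, table$response, n_stages = n_stages,
                    learning_rate = learning_rate, control = control)
  report <- split_gain_importance(model)
  kept <- character(0)
  for (name in report$feature) {
    if (length(kept) >= k) break
    if (length(kept) == 0L) {
      kept <- name
      next
    }
    r <- abs(stats::cor(table$descriptors[, name],
                        table$descriptors[, kept, drop = FALSE]))
    if (all(r < corr_threshold)) kept <- c(kept, name)
  }
  short <- length(kept) < k
  if (short) {
    warning(sprintf(
      "only %d of %d requested descriptors survive the |r| < %g filter",
      length(kept), k, corr_threshold), call. = FALSE)
  }
  list(selected = kept, report = report, warning = short)
}
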