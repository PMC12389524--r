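#' Configuration for a regression tree
#'
#' @param max_depth maximum tree depth (0 = a single leaf).
#' @param min_samples_split minimum node size eligible for splitting (>= 2).
#' @param min_samples_leaf minimum node size of each child after a split
#'   (>= 1).
#' @return An object of class `tree_config`.
#' @export
tree_config <- function(max_depth = 6L, min_samples_split = 2L,
                        min_samples_leaf = 1L) {
  max_depth <- as.integer(max_depth)
  min_samples_split <- as.integer(min_samples_split)
  min_samples_leaf <- as.integer(min_samples_leaf)
  if (max_depth < 0L) stop("max_depth must be >= 0", call. = FALSE)
  if (min_samples_split < 2L) stop("min_samples_split must be >= 2", call. = FALSE)
  if (min_samples_leaf < 1L) stop("min_samples_leaf must be >= 1", call. = FALSE)
  structure(list(max_depth = max_depth,
                 min_samples_split = min_samples_split,
                 min_samples_leaf = min_samples_leaf),
            class = "tree_config")
}

# Best split of one node over all features. Candidate thresholds are the
# midpoints between consecutive sorted unique values. The gain recorded is
# the decrease in total SSE achieved by the split (parent SSE minus the sum
# of the child SSEs). Ties in gain are broken by (feature index, threshold)
# in lexicographic order: the vectorized search scans features in column
# order and thresholds in increasing order, and only a strictly larger gain
# replaces the incumbent.
best_split <- function(X, y, min_samples_leaf) {
  n <- length(y)
  parent_sse <- sum(y^2) - sum(y)^2 / n
  best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
  for (f in seq_len(ncol(X))) {
    x <- X[, f]
    ord <- order(x)
    xs <- x[ord]
    ys <- y[ord]
    # split after position k: left = 1..k, right = (k+1)..n
    ks <- which(diff(xs) > 0)
    ks <- ks[ks >= min_samples_leaf & (n - ks) >= min_samples_leaf]
    if (length(ks) == 0L) next
    cs <- cumsum(ys)
    left_n <- ks
    right_n <- n - ks
    left_sum <- cs[ks]
    right_sum <- cs[n] - left_sum
    # gain = parent SSE - (left SSE + right SSE); the sum-of-squares terms
    # cancel, leaving the between-group decomposition below.
    gain <- left_sum^2 / left_n + right_sum^2 / right_n - cs[n]^2 / n
    k_best <- which.max(gain)
    if (gain[k_best] > best$gain + 1e-12 * max(parent_sse, 1)) {
      k <- ks[k_best]
      best <- list(gain = gain[k_best], feature = f,
                   threshold = (xs[k] + xs[k + 1L]) / 2)
    }
  }
  if (is.na(best$feature)) NULL else best
}

#' Fit a CART regression tree with recorded split gains
#'
#' Greedy binary recursive partitioning under the squared-error criterion.
#' Each internal node records the splitting feature and its squared-error
#' improvement (parent SSE minus child SSEs), which is the quantity
#' accumulated by [split_gain_importance()].
#'
#' @param X descriptor matrix.
#' @param y response vector.
#' @param config a [tree_config()].
#' @return An object of class `regression_tree`: a data.frame of nodes with
#'   columns `id`, `is_leaf`, `feature`, `threshold`, `value`, `gain`, `n`,
#'   `left`, `right`.
#' @export
fit_regression_tree <- function(X, y, config = tree_config()) {
  stopifnot(inherits(config, "tree_config"))
  X <- as.matrix(X)
  n <- length(y)
  if (n == 0L || nrow(X) != n) {
    stop("X and y must be non-empty with matching rows", call. = FALSE)
  }
  nodes <- list()
  new_node <- function(idx, depth) {
    id <- length(nodes) + 1L
    node <- list(id = id, is_leaf = TRUE, feature = NA_integer_,
                 threshold = NA_real_, value = mean(y[idx]), gain = NA_real_,
                 n = length(idx), left = NA_integer_, right = NA_integer_)
    nodes[[id]] <<- node
    if (depth < config$max_depth &&
        length(idx) >= config$min_samples_split &&
        length(idx) >= 2L * config$min_samples_leaf) {
      sp <- best_split(X[idx, , drop = FALSE], y[idx], config$min_samples_leaf)
      if (!is.null(sp)) {
        go_left <- X[idx, sp$feature] <= sp$threshold
        left_id <- new_node(idx[go_left], depth + 1L)
        right_id <- new_node(idx[!go_left], depth + 1L)
        nodes[[id]]$is_leaf <<- FALSE
        nodes[[id]]$feature <<- sp$feature
        nodes[[id]]$threshold <<- sp$threshold
        nodes[[id]]$gain <<- sp$gain
        nodes[[id]]$left <<- left_id
        nodes[[id]]$right <<- right_id
      }
    }
    id
  }
  new_node(seq_len(n), 0L)
  tree <- do.call(rbind, lapply(nodes, as.data.frame))
  structure(list(nodes = tree, n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "regression_tree")
}

#' @export
predict.regression_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  nodes <- object$nodes
  vapply(seq_len(nrow(X)), function(i) {
    id <- 1L
    while (!nodes$is_leaf[id]) {
      id <- if (X[i, nodes$feature[id]] <= nodes$threshold[id]) {
        nodes$left[id]
      } else {
        nodes$right[id]
      }
    }
    nodes$value[id]
  }, numeric(1))
}
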