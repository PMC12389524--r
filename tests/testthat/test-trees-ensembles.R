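test_that("regression trees honor depth and leaf constraints", {
  x <- matrix(seq(-1, 1, length.out = 20), 20, 1)
  y <- as.numeric(x[, 1] >= 0)
  # depth 0: single leaf at the mean
  leaf <- fit_regression_tree(x, y, tree_config(max_depth = 0))
  expect_equal(predict(leaf, x), rep(mean(y), 20))
  # depth 1 on step data: exhaustive threshold search says the optimum is a
  # single split between the sign change with zero training SSE
  tr <- fit_regression_tree(x, y, tree_config(max_depth = 1))
  split <- tr$nodes[!tr$nodes$is_leaf, ]
  expect_equal(nrow(split), 1L)
  expect_gt(split$threshold, max(x[x[, 1] < 0, 1]) - 1e-12)
  expect_lt(split$threshold, min(x[x[, 1] >= 0, 1]) + 1e-12)
  expect_equal(sum((predict(tr, x) - y)^2), 0)
  # min_samples_leaf = n forbids any split
  none <- fit_regression_tree(x, y, tree_config(max_depth = 5,
                                                min_samples_leaf = 20))
  expect_true(all(none$nodes$is_leaf))
  expect_error(fit_regression_tree(matrix(numeric(0), 0, 1), numeric(0)),
               "non-empty")
})

test_that("gbdt reduces training error stagewise and runs the published config", {
  ds <- linear_fixture(seed = 3)
  X <- ds$table$descriptors
  y <- ds$table$response
  g <- fit_gbdt(X, y, n_stages = 15, learning_rate = 0.3,
                control = tree_config(max_depth = 2))
  expect_true(all(diff(g$sse_trace) <= 1e-10))
  # single mean-only stage predicts mean(y) exactly
  g0 <- fit_gbdt(X, y, n_stages = 1, learning_rate = 1,
                 control = tree_config(max_depth = 0))
  expect_equal(predict(g0, X), rep(mean(y), length(y)))
  # the published configuration (11 stages, rate 0.08, depth 8) runs
  gp <- fit_gbdt(X, y, n_stages = 11, learning_rate = 0.08,
                 control = tree_config(max_depth = 8))
  expect_equal(gp$n_stages, 11L)
  expect_length(predict(gp, X), length(y))
})

test_that("random forests are seeded, average trees, and accept the published config", {
  ds <- linear_fixture(seed = 6, n = 40)
  X <- ds$table$descriptors
  y <- ds$table$response
  f1 <- fit_rf(X, y, n_trees = 25, control = tree_config(max_depth = 4), seed = 3)
  f2 <- fit_rf(X, y, n_trees = 25, control = tree_config(max_depth = 4), seed = 3)
  expect_identical(predict(f1, X), predict(f2, X))
  # a single tree without bootstrap equals a plain CART fit
  single <- fit_rf(X, y, n_trees = 1, control = tree_config(max_depth = 4),
                   seed = 1, bootstrap = FALSE)
  cart <- fit_regression_tree(X, y, tree_config(max_depth = 4))
  expect_equal(predict(single, X), predict(cart, X))
  # the published configuration: 575 trees, depth 6, min split 3, min leaf 3
  fp <- fit_rf(X, y, n_trees = 575,
               control = tree_config(max_depth = 6, min_samples_split = 3,
                                     min_samples_leaf = 3), seed = 5)
  expect_equal(fp$n_trees, 575L)
  expect_length(predict(fp, X[1:3, , drop = FALSE]), 3L)
})

test_that("forest predictions stabilize as trees are added", {
  ds <- linear_fixture(seed = 14, n = 40)
  X <- ds$table$descriptors
  y <- ds$table$response
  spread <- function(n_trees) {
    preds <- sapply(1:8, function(s)
      predict(fit_rf(X, y, n_trees = n_trees,
                     control = tree_config(max_depth = 3), seed = s),
              X[1:10, , drop = FALSE]))
    mean(apply(preds, 1, var))
  }
  expect_lt(spread(40), spread(3))
})

test_that("split-gain importance sums recorded gains and ranks stably", {
  ds <- linear_fixture(seed = 10, n = 80)
  X <- ds$table$descriptors
  y <- ds$table$response
  g <- fit_gbdt(X, y, n_stages = 10, learning_rate = 0.5,
                control = tree_config(max_depth = 2))
  rep <- split_gain_importance(g)
  expect_true(all(diff(rep$importance) <= 0))
  expect_equal(sum(rep$share), 1)
  expect_true(all(rep$importance >= 0))
  # single tree: the report equals an independent traversal of the nodes
  tree <- fit_regression_tree(X, y, tree_config(max_depth = 3))
  single <- fit_gbdt(X, y, n_stages = 1, learning_rate = 1,
                     control = tree_config(max_depth = 3))
  walk <- tapply(tree$nodes$gain[!tree$nodes$is_leaf],
                 tree$nodes$feature[!tree$nodes$is_leaf], sum)
  rep1 <- split_gain_importance(single)
  for (f in names(walk)) {
    name <- colnames(X)[as.integer(f)]
    expect_equal(rep1$importance[rep1$feature == name], unname(walk[[f]]))
  }
  # conservation: total importance equals the sum over internal nodes
  expect_equal(sum(rep1$importance), sum(tree$nodes$gain, na.rm = TRUE))
  # a feature never split on has exactly zero importance
  unused <- setdiff(colnames(X), colnames(X)[as.integer(names(walk))])
  expect_true(all(rep1$importance[rep1$feature %in% unused] == 0))
  expect_error(split_gain_importance(list()), "fitted")
})

test_that("the informative feature outranks pure noise", {
  ds <- make_synthetic_dataset(synthetic_config(
    n_compounds = 200, n_informative = 1, n_noise = 4, noise_sd = 0.2,
    response_kind = "linear", coefficients = 2, seed = 42))
  g <- fit_gbdt(ds$table$descriptors, ds$table$response, n_stages = 30,
                learning_rate = 0.2, control = tree_config(max_depth = 2))
  rep <- split_gain_importance(g)
  expect_equal(rep$feature[1], "inf1")
  expect_gt(rep$share[1], 0.5)
})

test_that("descriptor selection enforces the correlation filter", {
  # two identical columns: only one survives, with a warning
  set.seed(8)
  base <- rnorm(60)
  X <- cbind(a = base, b = base)
  tab <- descriptor_table(sprintf("c%02d", 1:60), X, base + rnorm(60, sd = 0.1))
  expect_warning(sel <- select_descriptors(tab, k = 2), "survive")
  expect_length(sel$selected, 1L)
  expect_true(sel$warning)

  # k = 4 from a rich table: exactly 4 names, pairwise |r| < 0.8
  ds <- make_synthetic_dataset(synthetic_config(
    n_compounds = 150, n_informative = 4, n_redundant = 2, n_noise = 4,
    redundancy_correlation = 0.9, noise_sd = 0.2, seed = 77))
  sel4 <- select_descriptors(ds$table, k = 4)
  expect_length(sel4$selected, 4L)
  cm <- abs(cor(ds$table$descriptors[, sel4$selected]))
  expect_true(all(cm[upper.tri(cm)] < 0.8))
})
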