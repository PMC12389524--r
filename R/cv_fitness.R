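#' Default hyperparameter search spaces per model family
#'
#' Box bounds used by the cross-validation fitness adapter. For the SVR
#' families the dimensions are the kernel and loss hyperparameters (with the
#' mixed-kernel weights constrained to the simplex by repair inside
#' [cv_fitness()]); for the tree ensembles they are the structural
#' hyperparameters, all but the learning rate integer-valued.
#'
#' @param model_family one of `"svr_poly"`, `"svr_mixed"`, `"rf"`, `"gbdt"`.
#' @return A [search_space()].
#' @export
default_search_space <- function(model_family = c("svr_poly", "svr_mixed",
                                                  "rf", "gbdt")) {
  switch(match.arg(model_family),
    svr_poly = search_space(
      lower = c(C = 0.01, epsilon = 0.001, gamma = 0.001, r = 0, d = 1),
      upper = c(C = 1000, epsilon = 0.5, gamma = 10, r = 2, d = 3),
      kind = c("real", "real", "real", "real", "integer"),
      names = c("C", "epsilon", "gamma", "r", "d")),
    svr_mixed = search_space(
      lower = c(C = 0.01, epsilon = 0.001, sigma = 0.001, gamma = 0.001,
                r = 0, d = 1, alpha = 0, beta = 0),
      upper = c(C = 1000, epsilon = 0.5, sigma = 100, gamma = 10,
                r = 2, d = 3, alpha = 1, beta = 1),
      kind = c(rep("real", 5), "integer", "real", "real"),
      names = c("C", "epsilon", "sigma", "gamma", "r", "d", "alpha", "beta")),
    rf = search_space(
      lower = c(n_trees = 50, max_depth = 2, min_split = 2, min_leaf = 1),
      upper = c(n_trees = 800, max_depth = 10, min_split = 10, min_leaf = 10),
      kind = "integer",
      names = c("n_trees", "max_depth", "min_split", "min_leaf")),
    gbdt = search_space(
      lower = c(n_stages = 5, learning_rate = 0.01, max_depth = 1),
      upper = c(n_stages = 300, learning_rate = 1, max_depth = 10),
      kind = c("integer", "real", "integer"),
      names = c("n_stages", "learning_rate", "max_depth"))
  )
}

# Euclidean projection of (alpha, beta) onto
# {a + b <= 1, 0 <= a, 0 <= b}: project onto the a + b = 1 face and clip.
project_simplex_face <- function(alpha, beta) {
  excess <- (alpha + beta - 1) / 2
  a <- min(1, max(0, alpha - excess))
  b <- min(1, max(0, beta - excess))
  if (a + b > 1) {  # clipping can re-violate at a corner
    if (a > b) a <- 1 - b else b <- 1 - a
  }
  c(alpha = a, beta = b)
}

# Build the model-fitting closure for one family from a named position.
family_fitter <- function(model_family, repair_env) {
  # A modest iteration cap keeps the search responsive: positions whose
  # dual solve cannot approach optimality quickly yield poor CV loss and
  # the swarm moves away from them.
  solver <- function(C, eps) {
    svr_config(cost = C, epsilon = eps, solver_tolerance = 1e-3,
               max_iterations = 3000L)
  }
  switch(model_family,
    svr_poly = function(pos, X, y) {
      spec <- kernel_spec("poly", gamma = pos[["gamma"]], offset = pos[["r"]],
                          degree = pos[["d"]])
      fit <- suppressWarnings(
        svr_train(X, y, spec, solver(pos[["C"]], pos[["epsilon"]])))
      function(Xq) predict(fit, Xq)
    },
    svr_mixed = function(pos, X, y) {
      a <- pos[["alpha"]]
      b <- pos[["beta"]]
      if (a + b > 1) {
        ab <- project_simplex_face(a, b)
        a <- ab[["alpha"]]
        b <- ab[["beta"]]
        repair_env$n_repaired <- repair_env$n_repaired + 1L
      }
      spec <- kernel_spec("mixed", gamma = pos[["gamma"]], offset = pos[["r"]],
                          degree = pos[["d"]], sigma = pos[["sigma"]],
                          weight_trig = a, weight_poly = b)
      fit <- suppressWarnings(
        svr_train(X, y, spec, solver(pos[["C"]], pos[["epsilon"]])))
      function(Xq) predict(fit, Xq)
    },
    rf = function(pos, X, y) {
      fit <- fit_rf(X, y, n_trees = pos[["n_trees"]],
                    tree_config(pos[["max_depth"]], pos[["min_split"]],
                                pos[["min_leaf"]]),
                    seed = repair_env$rf_seed)
      function(Xq) predict(fit, Xq)
    },
    gbdt = function(pos, X, y) {
      fit <- fit_gbdt(X, y, n_stages = pos[["n_stages"]],
                      learning_rate = pos[["learning_rate"]],
                      control = tree_config(pos[["max_depth"]]))
      function(Xq) predict(fit, Xq)
    },
    stop(sprintf("unknown model family '%s'", model_family), call. = FALSE)
  )
}

#' Fit a model family at a fixed hyperparameter position
#'
#' Companion to [cv_fitness()]: fits the named model family on `(X, y)` at
#' the given hyperparameter position (named as in
#' [default_search_space()]) and returns a prediction function. Mixed-kernel
#' weights with `alpha + beta > 1` are repaired by the same simplex
#' projection the fitness adapter applies, so the position returned by
#' [clpso_optimize()] can be passed straight through.
#'
#' @param model_family `"svr_poly"`, `"svr_mixed"`, `"rf"` or `"gbdt"`.
#' @param position named numeric vector of hyperparameters.
#' @param X training descriptor matrix.
#' @param y training response.
#' @param seed integer seed (used by the random-forest family).
#' @return `function(Xnew)` returning predictions.
#' @export
fit_at_position <- function(model_family, position, X, y, seed = 1L) {
  env <- new.env(parent = emptyenv())
  env$n_repaired <- 0L
  env$rf_seed <- as.integer(seed)
  space <- default_search_space(model_family)
  pos <- stats::setNames(round_integers(space, as.numeric(position)),
                         space$names)
  family_fitter(model_family, env)(pos, as.matrix(X), y)
}

#' Cross-validated fitness function for hyperparameter optimization
#'
#' Returns a closure mapping a hyperparameter position (in the order of
#' `space$names`) to the mean k-fold cross-validation loss on `table`, for
#' use with [clpso_optimize()] / [pso_optimize()]. Fold assignment is fixed
#' by `seed` at creation, so the fitness is deterministic. Mixed-kernel
#' weight positions with `alpha + beta > 1` are repaired by Euclidean
#' projection onto the simplex face; the number of repairs is available via
#' `attr(fn, "repairs")()`. Results are cached keyed by the rounded
#' position, so re-visited positions cost nothing.
#'
#' @param model_family `"svr_poly"`, `"svr_mixed"`, `"rf"` or `"gbdt"`.
#' @param table a [descriptor_table()] (all rows are used).
#' @param space the [search_space()] whose dimension names define the
#'   position layout; see [default_search_space()].
#' @param metric `"rmse"` (pooled out-of-fold RMSE) or `"one_minus_q2"`
#'   (1 - pooled cross-validated Q2).
#' @param folds number of CV folds.
#' @param seed integer seed fixing the fold assignment.
#' @return A fitness closure with attributes `repairs` (counter getter) and
#'   `cache_size` (getter).
#' @export
cv_fitness <- function(model_family, table, space,
                       metric = c("rmse", "one_minus_q2"),
                       folds = 5L, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(inherits(table, "descriptor_table"),
            inherits(space, "search_space"))
  n <- n_compounds(table)
  if (folds < 2L || folds > n) stop("folds must be in [2, n]", call. = FALSE)
  X <- table$descriptors
  y <- table$response
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  env <- new.env(parent = emptyenv())
  env$n_repaired <- 0L
  env$rf_seed <- as.integer(seed)
  env$cache <- new.env(parent = emptyenv())
  fitter <- family_fitter(model_family, env)

  fn <- function(position) {
    pos <- stats::setNames(round_integers(space, as.numeric(position)),
                           space$names)
    key <- paste(signif(pos, 10), collapse = ",")
    hit <- env$cache[[key]]
    if (!is.null(hit)) return(hit)
    pred <- numeric(n)
    ok <- tryCatch({
      for (k in seq_len(folds)) {
        hold <- fold_id == k
        predict_fold <- fitter(pos, X[!hold, , drop = FALSE], y[!hold])
        pred[hold] <- predict_fold(X[hold, , drop = FALSE])
      }
      TRUE
    }, error = function(e) FALSE)
    val <- if (!ok || any(!is.finite(pred))) {
      Inf
    } else if (metric == "rmse") {
      sqrt(mean((y - pred)^2))
    } else {
      1 - (1 - sum((y - pred)^2) / sum((y - mean(y))^2))
    }
    env$cache[[key]] <- val
    val
  }
  attr(fn, "repairs") <- function() env$n_repaired
  attr(fn, "cache_size") <- function() length(ls(env$cache))
  fn
}
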