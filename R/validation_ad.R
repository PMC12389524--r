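#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum (y - \hat y)^2 / \sum (y - \bar y)^2}, where
#' \eqn{\bar y} is the mean of `y` itself (not squared Pearson correlation).
#'
#' @param y observed values (not constant).
#' @param yhat predictions.
#' @return The scalar R^2 (can be negative for models worse than the mean).
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L) {
    stop("y and yhat must have equal length >= 2", call. = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R^2 is undefined for constant y", call. = FALSE)
  1 - sum((y - yhat)^2) / sst
}

#' Root mean square error
#'
#' `sqrt(mean((y - yhat)^2))` (divisor n).
#'
#' @param y observed values.
#' @param yhat predictions.
#' @return The scalar RMSE.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 1L) {
    stop("y and yhat must have equal length >= 1", call. = FALSE)
  }
  sqrt(mean((y - yhat)^2))
}

# A model factory is function(X, y) returning a predictor function(Xnew).
ols_factory <- function(X, y) {
  Xi <- cbind(1, X)
  beta <- qr.coef(qr(Xi), y)
  function(Xnew) drop(cbind(1, as.matrix(Xnew)) %*% beta)
}

#' Leave-one-out cross-validated Q^2
#'
#' Refits the model n times leaving each compound out in turn;
#' \eqn{Q^2 = 1 - PRESS / \sum (y - \bar y)^2} with \eqn{\bar y} the mean of
#' the full response.
#'
#' @param model_factory `function(X, y)` returning a predictor
#'   `function(Xnew) -> numeric`.
#' @param table a [descriptor_table()].
#' @return The scalar Q^2 (LOO).
#' @export
q2_loo <- function(model_factory, table) {
  stopifnot(inherits(table, "descriptor_table"))
  n <- n_compounds(table)
  if (n < 3L) stop("need at least 3 compounds for LOO", call. = FALSE)
  X <- table$descriptors
  y <- table$response
  pred <- vapply(seq_len(n), function(i) {
    predictor <- tryCatch(
      model_factory(X[-i, , drop = FALSE], y[-i]),
      error = function(e) stop(sprintf("model factory failed on fold %d: %s",
                                       i, conditionMessage(e)), call. = FALSE))
    predictor(X[i, , drop = FALSE])[1L]
  }, numeric(1))
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' k-fold cross-validated Q^2
#'
#' Seeded shuffle, contiguous near-equal folds, pooled out-of-fold
#' predictions: \eqn{Q^2 = 1 - SSE_{pooled} / \sum (y - \bar y)^2}. With
#' `k = n` this reduces exactly to [q2_loo()].
#'
#' @inheritParams q2_loo
#' @param k number of folds (2..n).
#' @param seed integer seed for the fold shuffle.
#' @return The scalar Q^2 (k-fold).
#' @export
q2_kfold <- function(model_factory, table, k = 5L, seed = 1L) {
  stopifnot(inherits(table, "descriptor_table"))
  n <- n_compounds(table)
  if (k < 2L || k > n) stop("k must be in [2, n]", call. = FALSE)
  X <- table$descriptors
  y <- table$response
  perm <- with_seed(seed, sample.int(n))
  bounds <- floor(seq(0, n, length.out = k + 1L))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    hold <- perm[(bounds[f] + 1L):bounds[f + 1L]]
    predictor <- tryCatch(
      model_factory(X[-hold, , drop = FALSE], y[-hold]),
      error = function(e) stop(sprintf("model factory failed on fold %d: %s",
                                       f, conditionMessage(e)), call. = FALSE))
    pred[hold] <- predictor(X[hold, , drop = FALSE])
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Lin's concordance correlation coefficient
#'
#' \eqn{CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)} with 1/n
#' moments; an agreement measure penalizing both dispersion and location
#' shifts, so it is at most |Pearson r|.
#'
#' @param y observed values.
#' @param yhat predictions.
#' @return The scalar CCC in \[-1, 1\].
#' @export
ccc <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L) {
    stop("y and yhat must have equal length >= 2", call. = FALSE)
  }
  n <- length(y)
  mx <- mean(y)
  my <- mean(yhat)
  sx2 <- mean((y - mx)^2)
  sy2 <- mean((yhat - my)^2)
  sxy <- mean((y - mx) * (yhat - my))
  if (sx2 == 0 && sy2 == 0) {
    stop("CCC is undefined for two constant sequences", call. = FALSE)
  }
  denom <- sx2 + sy2 + (mx - my)^2
  2 * sxy / denom
}

#' External validation QF^2 statistics
#'
#' \deqn{Q_{F1}^2 = 1 - \sum (y_{test} - \hat y)^2 /
#'   \sum (y_{test} - \bar y_{train})^2}
#' \deqn{Q_{F2}^2 = 1 - \sum (y_{test} - \hat y)^2 /
#'   \sum (y_{test} - \bar y_{test})^2}
#'
#' @param y_test test-set observations (length >= 2).
#' @param yhat_test test-set predictions.
#' @param y_train_mean mean of the training responses.
#' @return Named numeric vector `c(qf1, qf2)`.
#' @export
qf_metrics <- function(y_test, yhat_test, y_train_mean) {
  if (length(y_test) != length(yhat_test) || length(y_test) < 2L) {
    stop("y_test and yhat_test must have equal length >= 2", call. = FALSE)
  }
  sse <- sum((y_test - yhat_test)^2)
  d1 <- sum((y_test - y_train_mean)^2)
  d2 <- sum((y_test - mean(y_test))^2)
  if (d1 == 0 || d2 == 0) stop("zero denominator in QF^2", call. = FALSE)
  c(qf1 = 1 - sse / d1, qf2 = 1 - sse / d2)
}

#' y-randomization (response scrambling) test
#'
#' Permutes the response with a seeded generator, refits the model with
#' fixed hyperparameters, and records the training R^2 and LOO Q^2 of each
#' scrambled model. A model free of chance correlation shows low values in
#' every repeat.
#'
#' @param model_factory `function(X, y)` returning a predictor.
#' @param table a [descriptor_table()].
#' @param n_repeats number of scrambles (default 10).
#' @param seed integer seed.
#' @return A data.frame with columns `repeat_id`, `r2_yrand`, `q2_yrand`,
#'   with `max_r2`, `mean_r2`, `max_q2` attached as attributes.
#' @export
y_randomization <- function(model_factory, table, n_repeats = 10L, seed = 1L) {
  stopifnot(inherits(table, "descriptor_table"))
  n <- n_compounds(table)
  perms <- with_seed(seed, replicate(n_repeats, sample.int(n), simplify = FALSE))
  rows <- lapply(seq_len(n_repeats), function(rep_i) {
    scrambled <- table
    scrambled$response <- table$response[perms[[rep_i]]]
    predictor <- model_factory(scrambled$descriptors, scrambled$response)
    r2 <- r_squared(scrambled$response, predictor(scrambled$descriptors))
    q2 <- q2_loo(model_factory, scrambled)
    data.frame(repeat_id = rep_i, r2_yrand = r2, q2_yrand = q2)
  })
  out <- do.call(rbind, rows)
  attr(out, "max_r2") <- max(out$r2_yrand)
  attr(out, "mean_r2") <- mean(out$r2_yrand)
  attr(out, "max_q2") <- max(out$q2_yrand)
  out
}

#' Leverage of query compounds against a training design
#'
#' \eqn{h_i = x_i^T (X^T X)^{-1} x_i} where X is the training descriptor
#' matrix (with an intercept column when `intercept = TRUE`, the default).
#' Training leverages sum to the number of model parameters p (the trace of
#' the hat matrix).
#'
#' @param X_train training descriptor matrix.
#' @param X_query query descriptor matrix (defaults to the training matrix).
#' @param intercept prepend an intercept column to both matrices.
#' @return Numeric vector of leverages, one per query row.
#' @export
leverage <- function(X_train, X_query = X_train, intercept = TRUE) {
  X_train <- as.matrix(X_train)
  X_query <- as.matrix(X_query)
  if (ncol(X_train) != ncol(X_query)) {
    stop("X_train and X_query must have the same columns", call. = FALSE)
  }
  if (intercept) {
    X_train <- cbind(1, X_train)
    X_query <- cbind(1, X_query)
  }
  xtx <- crossprod(X_train)
  inv <- tryCatch(solve(xtx), error = function(e) {
    warning("X'X is singular; using the pseudoinverse", call. = FALSE)
    s <- svd(xtx)
    pos <- s$d > max(s$d) * 1e-12
    s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  })
  rowSums((X_query %*% inv) * X_query)
}

#' Williams applicability-domain report
#'
#' Computes leverages against the training descriptors, the warning
#' leverage \eqn{h^* = 3p/n} (n = training-set size), standardized residuals
#' (residual divided by the standard deviation of the training residuals)
#' and the Williams classification of every compound:
#' `response_outlier` when |standardized residual| > 3,
#' `influential` when \eqn{h > h^*} with residual within the band, else
#' `in_domain`.
#'
#' @param table a [descriptor_table()] with split flags set.
#' @param predictions predicted response for every row of `table`.
#' @param p number of model parameters for `h*` (descriptors + intercept).
#' @return An `ad_report` list: per-compound data.frame (`compound_id`,
#'   `split`, `leverage`, `std_residual`, `classification`), `h_star`,
#'   `p`, `n_train`, `residual_sd` and per-class `counts`.
#' @export
williams_report <- function(table, predictions, p) {
  stopifnot(inherits(table, "descriptor_table"))
  if (length(predictions) != n_compounds(table)) {
    stop("predictions must match the table rows", call. = FALSE)
  }
  train <- table$split_flag == "train"
  if (!any(train)) stop("table has no training rows flagged", call. = FALSE)
  n <- sum(train)
  h_star <- 3 * p / n
  residuals <- table$response - predictions
  sd_train <- stats::sd(residuals[train])
  if (!is.finite(sd_train) || sd_train == 0) {
    stop("training residual standard deviation is zero", call. = FALSE)
  }
  std_res <- residuals / sd_train
  h <- leverage(table$descriptors[train, , drop = FALSE], table$descriptors)
  classification <- ifelse(abs(std_res) > 3, "response_outlier",
                           ifelse(h > h_star, "influential", "in_domain"))
  report <- data.frame(compound_id = table$compound_ids,
                       split = table$split_flag,
                       leverage = h,
                       std_residual = std_res,
                       classification = classification,
                       stringsAsFactors = FALSE)
  structure(list(compounds = report, h_star = h_star, p = p, n_train = n,
                 residual_sd = sd_train,
                 counts = table(factor(classification,
                                       c("in_domain", "response_outlier",
                                         "influential")))),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("<ad_report> h* = %.5f (p = %d, n_train = %d)\n",
              x$h_star, x$p, x$n_train))
  print(x$counts)
  invisible(x)
}

#' Default acceptability thresholds for QSAR validation statistics
#'
#' The conventional empirical acceptability rules: R^2 > 0.7,
#' Q^2(LOO) > 0.6, Q^2(5-fold) > 0.55, CCC > 0.85 and QF^2 > 0.7.
#'
#' @return Named numeric vector of thresholds.
#' @export
validation_thresholds <- function() {
  c(r2 = 0.7, q2_loo = 0.6, q2_5fold = 0.55, ccc = 0.85, qf2 = 0.7)
}

#' Assemble a validation report with pass/fail flags
#'
#' @param r2_train,rmse_train,r2_test,rmse_test fit statistics.
#' @param q2_loo,q2_5fold internal validation statistics.
#' @param ccc,qf1,qf2 external validation statistics.
#' @param thresholds named thresholds, defaulting to
#'   [validation_thresholds()].
#' @return A `validation_report` list with `statistics`, `thresholds` and
#'   logical `pass`.
#' @export
validation_report <- function(r2_train, rmse_train, r2_test, rmse_test,
                              q2_loo = NA_real_, q2_5fold = NA_real_,
                              ccc = NA_real_, qf1 = NA_real_, qf2 = NA_real_,
                              thresholds = validation_thresholds()) {
  stats <- c(r2_train = r2_train, rmse_train = rmse_train,
             r2_test = r2_test, rmse_test = rmse_test,
             q2_loo = q2_loo, q2_5fold = q2_5fold,
             ccc = ccc, qf1 = qf1, qf2 = qf2)
  pass <- c(r2_train = unname(stats["r2_train"] > thresholds["r2"]),
            r2_test = unname(stats["r2_test"] > thresholds["r2"]),
            q2_loo = unname(stats["q2_loo"] > thresholds["q2_loo"]),
            q2_5fold = unname(stats["q2_5fold"] > thresholds["q2_5fold"]),
            ccc = unname(stats["ccc"] > thresholds["ccc"]),
            qf1 = unname(stats["qf1"] > thresholds["qf2"]),
            qf2 = unname(stats["qf2"] > thresholds["qf2"]))
  structure(list(statistics = stats, thresholds = thresholds, pass = pass),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  for (nm in names(x$statistics)) {
    flag <- if (nm %in% names(x$pass)) {
      if (is.na(x$pass[[nm]])) " (not assessed)" else if (x$pass[[nm]]) " [pass]" else " [FAIL]"
    } else ""
    cat(sprintf("  %-9s %8.4f%s\n", nm, x$statistics[[nm]], flag))
  }
  invisible(x)
}
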