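#' Pre-filter descriptors for linear modeling
#'
#' Applies, in order, the standard descriptor pre-selection rules for
#' heuristic linear QSAR model building:
#' \enumerate{
#'   \item drop constant columns;
#'   \item drop columns whose one-descriptor regression F statistic is below
#'     `f_min`;
#'   \item for every pair with |Pearson r| above `corr_threshold`, drop the
#'     member with the lower single-descriptor R^2;
#'   \item drop columns whose one-descriptor regression |t| is below `t_min`.
#' }
#'
#' @param table a [descriptor_table()].
#' @param corr_threshold pairwise correlation bound (default 0.8).
#' @param f_min minimum one-parameter F statistic (default 1.0).
#' @param t_min minimum one-parameter |t| statistic (default 1.96,
#'   user-overridable).
#' @return A list with `table` (the reduced [descriptor_table()]) and
#'   `removal_log` (data.frame of `column`, `rule`, `statistic`).
#' @export
prefilter_descriptors <- function(table, corr_threshold = 0.8, f_min = 1.0,
                                  t_min = 1.96) {
  stopifnot(inherits(table, "descriptor_table"))
  X <- table$descriptors
  y <- table$response
  n <- length(y)
  log <- data.frame(column = character(0), rule = character(0),
                    statistic = numeric(0), stringsAsFactors = FALSE)
  drop_cols <- function(cols, rule, stat) {
    log <<- rbind(log, data.frame(column = cols, rule = rule,
                                  statistic = stat, stringsAsFactors = FALSE))
    X <<- X[, setdiff(colnames(X), cols), drop = FALSE]
  }

  sds <- apply(X, 2, stats::sd)
  constant <- colnames(X)[sds < 1e-12]
  if (length(constant)) drop_cols(constant, "constant", 0)

  # one-descriptor regression statistics from the correlation with y:
  # t = r sqrt((n-2)/(1-r^2)), F = t^2, R^2 = r^2
  one_param <- function() {
    r <- drop(stats::cor(X, y))
    r2 <- pmin(r^2, 1 - 1e-15)
    t <- r * sqrt((n - 2) / (1 - r2))
    list(r2 = r^2, t = t, f = t^2)
  }

  if (ncol(X) > 0L) {
    st <- one_param()
    low_f <- colnames(X)[st$f < f_min]
    if (length(low_f)) drop_cols(low_f, "low_F", st$f[st$f < f_min])
  }

  if (ncol(X) > 1L) {
    st <- one_param()
    cm <- abs(stats::cor(X))
    # resolve pairs in column order; within a pair keep the more predictive
    removed <- character(0)
    removed_r <- numeric(0)
    for (a in seq_len(ncol(X) - 1L)) {
      for (b in seq((a + 1L), ncol(X))) {
        ca <- colnames(X)[a]
        cb <- colnames(X)[b]
        if (ca %in% removed || cb %in% removed) next
        if (cm[a, b] > corr_threshold) {
          victim <- if (st$r2[a] >= st$r2[b]) cb else ca
          removed <- c(removed, victim)
          removed_r <- c(removed_r, cm[a, b])
        }
      }
    }
    if (length(removed)) drop_cols(removed, "correlated", removed_r)
  }

  if (ncol(X) > 0L) {
    st <- one_param()
    low_t <- colnames(X)[abs(st$t) < t_min]
    if (length(low_t)) drop_cols(low_t, "low_t", st$t[abs(st$t) < t_min])
  }

  if (ncol(X) == 0L) {
    stop(paste0("all descriptors removed by pre-filtering; removal log:\n",
                paste(utils::capture.output(print(log)), collapse = "\n")),
         call. = FALSE)
  }
  table$descriptors <- X
  list(table = table, removal_log = log)
}

#' Fit an ordinary least squares QSAR model
#'
#' Least-squares fit with intercept on the named descriptors, via
#' [stats::lm()].
#'
#' @param table a [descriptor_table()].
#' @param descriptor_names columns of the descriptor matrix to use.
#' @return An object of class `linear_model` with `intercept`,
#'   `coefficients` (named), `r2`, `rmse`, `t_values`, `f_statistic` and the
#'   underlying `lm` fit.
#' @export
fit_ols <- function(table, descriptor_names) {
  stopifnot(inherits(table, "descriptor_table"))
  missing <- setdiff(descriptor_names, colnames(table$descriptors))
  if (length(missing)) {
    stop(sprintf("unknown descriptors: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  n <- n_compounds(table)
  if (n <= length(descriptor_names)) {
    stop("need more compounds than descriptors (n > p)", call. = FALSE)
  }
  df <- as.data.frame(table$descriptors[, descriptor_names, drop = FALSE])
  df$.response <- table$response
  fit <- stats::lm(.response ~ ., data = df)
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(names(coefs)[is.na(coefs)], collapse = ", ")),
         call. = FALSE)
  }
  sm <- summary(fit)
  structure(
    list(intercept = unname(coefs[1L]),
         coefficients = coefs[-1L],
         r2 = sm$r.squared,
         rmse = sqrt(mean(stats::residuals(fit)^2)),
         t_values = sm$coefficients[, "t value"],
         f_statistic = if (length(descriptor_names)) unname(sm$fstatistic[1L]) else NA_real_,
         lm_fit = fit),
    class = "linear_model"
  )
}

#' @export
print.linear_model <- function(x, ...) {
  cat("<linear_model>\n  intercept:", format(x$intercept), "\n")
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %s: %s\n", nm, format(x$coefficients[[nm]])))
  }
  cat(sprintf("  R2 = %.4f, RMSE = %.4f\n", x$r2, x$rmse))
  invisible(x)
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, names(object$coefficients), drop = FALSE]
  drop(X %*% object$coefficients) + object$intercept
}

#' Greedy forward selection with R^2 and leave-one-out R^2cv
#'
#' At each size k the descriptor maximizing training R^2 is added to the
#' model. The reported `r2_cv` is the leave-one-out cross-validated R^2,
#' computed exactly via the PRESS identity for OLS
#' (`PRESS = sum((residual / (1 - leverage))^2)`), which equals refitting
#' with each compound left out in turn. The resulting (k, R^2, R^2cv) curve
#' supports the usual elbow analysis of descriptor count against model
#' quality.
#'
#' @param table a [descriptor_table()].
#' @param max_k largest model size to consider.
#' @return A data.frame with one row per k: `k`, `descriptors`
#'   (comma-joined names in selection order), `r2`, `r2_cv`.
#' @export
forward_select <- function(table, max_k) {
  stopifnot(inherits(table, "descriptor_table"))
  p <- ncol(table$descriptors)
  if (max_k < 1L || max_k > p) {
    stop("max_k must be between 1 and the descriptor count", call. = FALSE)
  }
  y <- table$response
  sst <- sum((y - mean(y))^2)
  chosen <- character(0)
  rows <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    candidates <- setdiff(colnames(table$descriptors), chosen)
    best <- NULL
    for (cand in candidates) {
      cols <- c(chosen, cand)
      Xk <- cbind(1, table$descriptors[, cols, drop = FALSE])
      qr_fit <- stats::lm.fit(Xk, y)
      r2 <- 1 - sum(qr_fit$residuals^2) / sst
      if (is.null(best) || r2 > best$r2 + 1e-12) {
        best <- list(name = cand, r2 = r2, fit = qr_fit, X = Xk)
      }
    }
    chosen <- c(chosen, best$name)
    h <- stats::hat(best$X, intercept = FALSE)
    press <- sum((best$fit$residuals / (1 - h))^2)
    rows[[k]] <- data.frame(k = k,
                            descriptors = paste(chosen, collapse = ","),
                            r2 = best$r2,
                            r2_cv = 1 - press / sst,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Apply the published heuristic-method linear model
#'
#' Evaluates the published three-descriptor linear model for lg(IC50) of
#' EGFR L858R/T790M/C797S inhibitors:
#' \deqn{lg IC_{50} = -7.3731 - 40.041 \cdot RS + 0.48875 \cdot NR
#'   + 0.80855 \cdot ME}
#' where RS is the relative number of S atoms, NR the number of rings and
#' ME the maximum exchange energy for a C-N bond.
#'
#' @param rs relative number of S atoms.
#' @param nr number of rings.
#' @param me maximum exchange energy for a C-N bond.
#' @return Predicted lg(IC50) (IC50 in nM).
#' @export
apply_hm_model <- function(rs, nr, me) {
  -7.3731 - 40.041 * rs + 0.48875 * nr + 0.80855 * me
}
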