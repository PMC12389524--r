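#' Configuration for the synthetic QSAR data generator
#'
#' Describes the statistical structure the generator emulates: a few
#' informative descriptors that truly drive the response, redundant
#' descriptors correlated with informative ones strongly enough
#' (correlation > 0.8) that a correlation filter should drop them, and
#' pure-noise descriptors.
#'
#' @param n_compounds number of rows to generate.
#' @param n_informative number of informative descriptors (>= 1).
#' @param n_redundant number of redundant descriptors, each a noisy copy of
#'   an informative column at correlation `redundancy_correlation`.
#' @param n_noise number of irrelevant standard-normal descriptors.
#' @param redundancy_correlation target Pearson correlation between each
#'   redundant column and its parent; must exceed 0.8 so redundant columns
#'   fail the 0.8 correlation filter.
#' @param noise_sd standard deviation of Gaussian response noise (lg units).
#' @param response_kind `"linear"` (linear combination of informative
#'   descriptors) or `"kernel_nonlinear"` (sum of cosines of scaled squared
#'   distances to anchor points, i.e. a target realizable by the
#'   trigonometric kernel).
#' @param coefficients optional numeric vector of length `n_informative`
#'   used by the linear response; defaults to an alternating +/- ramp.
#' @param seed integer seed; identical configs with identical seeds
#'   generate identical tables.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_compounds = 100,
                             n_informative = 3,
                             n_redundant = 0,
                             n_noise = 0,
                             redundancy_correlation = 0.95,
                             noise_sd = 0.1,
                             response_kind = c("linear", "kernel_nonlinear"),
                             coefficients = NULL,
                             seed = 1) {
  response_kind <- match.arg(response_kind)
  if (n_informative < 1L) {
    stop("configuration error: n_informative must be >= 1", call. = FALSE)
  }
  if (n_redundant > 0L &&
      (redundancy_correlation <= 0.8 || redundancy_correlation > 1)) {
    stop("configuration error: redundancy_correlation must lie in (0.8, 1]",
         call. = FALSE)
  }
  if (noise_sd < 0) {
    stop("configuration error: noise_sd must be nonnegative", call. = FALSE)
  }
  if (!is.null(coefficients) && length(coefficients) != n_informative) {
    stop("configuration error: coefficients length must equal n_informative",
         call. = FALSE)
  }
  if (is.null(coefficients) && response_kind == "linear") {
    coefficients <- rep_len(c(1, -1), n_informative) *
      seq(2, 1, length.out = n_informative)
  }
  structure(
    list(n_compounds = n_compounds, n_informative = n_informative,
         n_redundant = n_redundant, n_noise = n_noise,
         redundancy_correlation = redundancy_correlation,
         noise_sd = noise_sd, response_kind = response_kind,
         coefficients = coefficients, seed = seed),
    class = "synthetic_config"
  )
}

#' Generate a synthetic QSAR dataset
#'
#' Informative descriptors are i.i.d. standard normal. Each redundant
#' descriptor is `rho * parent + sqrt(1 - rho^2) * z` with fresh standard
#' normal `z`, which has Pearson correlation `rho` with its parent in
#' expectation. The linear response is `descriptors %*% coefficients`; the
#' kernel-nonlinear response is a sum of cosines of scaled squared
#' Euclidean distances to a few anchor points drawn from the same
#' distribution as the data (so it lies in the hypothesis class of the
#' trigonometric kernel). Gaussian noise of sd `noise_sd` is added last.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `table` (a [descriptor_table()]) and
#'   `ground_truth` (generating coefficients or anchor description, the
#'   noise-free response, and the informative/redundant/noise column names).
#' @export
make_synthetic_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_compounds
    p_inf <- cfg$n_informative
    X_inf <- matrix(stats::rnorm(n * p_inf), n, p_inf)
    inf_names <- paste0("inf", seq_len(p_inf))
    colnames(X_inf) <- inf_names

    red_names <- character(0)
    X_red <- matrix(numeric(0), n, 0)
    parents <- integer(0)
    if (cfg$n_redundant > 0L) {
      rho <- cfg$redundancy_correlation
      parents <- rep_len(seq_len(p_inf), cfg$n_redundant)
      X_red <- sapply(parents, function(j) {
        rho * X_inf[, j] + sqrt(1 - rho^2) * stats::rnorm(n)
      })
      X_red <- matrix(X_red, n, cfg$n_redundant)
      red_names <- paste0("red", seq_len(cfg$n_redundant))
      colnames(X_red) <- red_names
    }

    noise_names <- character(0)
    X_noise <- matrix(numeric(0), n, 0)
    if (cfg$n_noise > 0L) {
      X_noise <- matrix(stats::rnorm(n * cfg$n_noise), n, cfg$n_noise)
      noise_names <- paste0("noise", seq_len(cfg$n_noise))
      colnames(X_noise) <- noise_names
    }

    if (cfg$response_kind == "linear") {
      signal <- drop(X_inf %*% cfg$coefficients)
      truth <- list(kind = "linear", coefficients = cfg$coefficients)
    } else {
      # 4 anchors from the data distribution; length scales chosen so the
      # cosine arguments stay in a low number of periods across the cloud,
      # keeping the surface smooth but genuinely nonlinear.
      n_anchor <- 4L
      anchors <- matrix(stats::rnorm(n_anchor * p_inf), n_anchor, p_inf)
      scales <- stats::runif(n_anchor, 0.1, 0.4) / p_inf
      amps <- stats::runif(n_anchor, 0.5, 1.5)
      d2 <- outer(rowSums(X_inf^2), rowSums(anchors^2), "+") -
        2 * X_inf %*% t(anchors)
      signal <- drop(cos(sweep(d2, 2, scales, "*")) %*% amps)
      truth <- list(kind = "kernel_nonlinear", anchors = anchors,
                    scales = scales, amplitudes = amps)
    }
    y <- signal + if (cfg$noise_sd > 0) stats::rnorm(n, sd = cfg$noise_sd) else 0

    X <- cbind(X_inf, X_red, X_noise)
    table <- descriptor_table(
      compound_ids = sprintf("synth%03d", seq_len(n)),
      descriptors = X,
      response = y
    )
    truth$signal <- signal
    truth$informative <- inf_names
    truth$redundant <- red_names
    truth$redundant_parent <- if (length(parents)) inf_names[parents] else character(0)
    truth$noise <- noise_names
    list(table = table, ground_truth = truth)
  })
}
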