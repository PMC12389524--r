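#' Configuration for the epsilon-SVR dual solver
#'
#' @param cost penalty parameter C (> 0) trading margin flatness against
#'   slack penalties.
#' @param epsilon half-width of the epsilon-insensitive tube (>= 0).
#' @param solver_tolerance stopping tolerance on the maximal KKT violation
#'   of the dual (difference between the most violating pair of gradient
#'   bounds). Interpreted relative to the kernel scale when Gram entries
#'   are large (the violation bound is `solver_tolerance * max(1,
#'   max(abs(diag(gram))))`), since an absolute bound below the resolution
#'   of double-precision gradients is not attainable.
#' @param max_iterations cap on SMO pair updates.
#' @return An object of class `svr_config`.
#' @export
svr_config <- function(cost = 1, epsilon = 0.1,
                       solver_tolerance = 1e-6, max_iterations = 200000L) {
  if (cost <= 0) stop("cost must be > 0", call. = FALSE)
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  if (solver_tolerance <= 0) stop("solver_tolerance must be > 0", call. = FALSE)
  structure(list(cost = cost, epsilon = epsilon,
                 solver_tolerance = solver_tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "svr_config")
}

# Project a symmetric matrix onto the PSD cone by clipping negative
# eigenvalues at zero. The trigonometric (and hence mixed) kernel is not
# provably positive semidefinite, so the training Gram is regularized this
# way before the convex dual solve; prediction uses the original kernel.
# Returns the clipped matrix with the clipped spectral mass as an attribute.
psd_clip <- function(K, tol = 1e-10) {
  e <- eigen(K, symmetric = TRUE)
  neg <- e$values < 0
  clipped_mass <- sum(abs(e$values[neg]))
  if (clipped_mass <= tol * max(abs(e$values), 1)) {
    attr(K, "clipped_mass") <- 0
    return(K)
  }
  vals <- pmax(e$values, 0)
  Kc <- e$vectors %*% (vals * t(e$vectors))
  Kc <- (Kc + t(Kc)) / 2
  attr(Kc, "clipped_mass") <- clipped_mass
  Kc
}

#' Fit epsilon-SVR on a precomputed Gram matrix
#'
#' Solves the standard dual of epsilon-insensitive support vector
#' regression,
#' \deqn{\min_{\alpha,\alpha^*} \tfrac12 (\alpha-\alpha^*)^T K
#'   (\alpha-\alpha^*) + \epsilon \sum_i (\alpha_i + \alpha_i^*) -
#'   \sum_i y_i (\alpha_i - \alpha_i^*)}
#' subject to \eqn{\sum_i (\alpha_i - \alpha_i^*) = 0} and
#' \eqn{0 \le \alpha_i, \alpha_i^* \le C}, by sequential minimal
#' optimization with maximal-violating-pair working-set selection. If the
#' Gram matrix is indefinite (possible for the trigonometric and mixed
#' kernels) it is first projected onto the PSD cone by eigenvalue clipping;
#' the clipped spectral mass is recorded on the returned model.
#'
#' The fitted predictor is \eqn{f(x) = \sum_j (\alpha_j - \alpha_j^*)
#' K(x_j, x) + b}. The bias is the mean of the values implied by the free
#' support vectors (those with \eqn{0 < \alpha^{(*)} < C}); when none are
#' free it is the midpoint of the KKT-feasible interval.
#'
#' @param gram square symmetric training Gram matrix.
#' @param y numeric response vector matching `gram`.
#' @param config an [svr_config()].
#' @return An object of class `svr_model` with elements `dual_coefficients`
#'   (\eqn{\alpha_j - \alpha_j^*}), `bias`, `support_indices`, `converged`,
#'   `iterations`, `kkt_violation`, `dual_objective`, `clipped_mass` and the
#'   config used.
#' @export
fit_svr <- function(gram, y, config = svr_config()) {
  stopifnot(inherits(config, "svr_config"))
  gram <- as.matrix(gram)
  n <- length(y)
  if (nrow(gram) != n || ncol(gram) != n) {
    stop("gram must be square with dimensions matching y", call. = FALSE)
  }
  if (max(abs(gram - t(gram))) > 1e-8 * max(1, max(abs(gram)))) {
    stop("gram must be symmetric", call. = FALSE)
  }
  K <- psd_clip((gram + t(gram)) / 2)
  clipped_mass <- attr(K, "clipped_mass")
  C <- config$cost
  eps <- config$epsilon
  tol <- config$solver_tolerance

  # Combined variable vector theta = (alpha, alpha*), signs z = (+1, -1),
  # gradient G = Q theta + p with p = (eps - y, eps + y) and
  # Q = [K, -K; -K, K]. Column t of Q is z_t * c(K[, m], -K[, m]) where m is
  # the training index of t.
  z <- rep(c(1, -1), each = n)
  m_of <- rep(seq_len(n), 2L)
  theta <- numeric(2L * n)
  G <- c(eps - y, eps + y)
  diagQ <- rep(diag(K), 2L)
  # Stopping is relative to the kernel scale: for Gram entries of order
  # 10^8 (large polynomial components) an absolute 1e-3 violation is below
  # the resolution of double-precision gradients.
  scale <- max(1, max(abs(diag(K))))
  tol_eff <- tol * scale
  refresh_every <- max(4L * n, 100L)

  it <- 0L
  violation <- Inf
  repeat {
    if (it > 0L && it %% refresh_every == 0L) {
      # recompute the gradient from scratch to cancel incremental drift
      beta_now <- theta[1:n] - theta[(n + 1L):(2L * n)]
      v <- drop(K %*% beta_now)
      G <- c(v, -v) + c(eps - y, eps + y)
    }
    # I_up: theta can move in the +z direction; I_low: in the -z direction.
    up <- (z > 0 & theta < C) | (z < 0 & theta > 0)
    low <- (z > 0 & theta > 0) | (z < 0 & theta < C)
    nzG <- -z * G
    i <- which(up)[which.max(nzG[up])]
    j <- which(low)[which.min(nzG[low])]
    violation <- nzG[i] - nzG[j]
    if (!is.finite(violation) || violation <= tol_eff ||
        it >= config$max_iterations) break

    # curvature along the feasible direction (d_i, d_j) = (z_i, -z_j):
    # d'Qd = K_ii + K_jj - 2 K_ij regardless of which block i and j are in
    a <- diagQ[i] + diagQ[j] - 2 * K[m_of[i], m_of[j]]
    a <- max(a, 1e-12)
    s <- (nzG[i] - nzG[j]) / a
    # box clip along direction d_i = z_i, d_j = -z_j
    cap_i <- if (z[i] > 0) C - theta[i] else theta[i]
    cap_j <- if (z[j] > 0) theta[j] else C - theta[j]
    s <- min(s, cap_i, cap_j)
    if (s <= 0) break  # numerically stuck; KKT violation reported below

    theta[i] <- theta[i] + z[i] * s
    theta[j] <- theta[j] - z[j] * s
    Ki <- K[, m_of[i]]
    Kj <- K[, m_of[j]]
    G <- G + (s * z[i] * z[i]) * c(Ki, -Ki) - (s * z[j] * z[j]) * c(Kj, -Kj)
    it <- it + 1L
  }
  converged <- is.finite(violation) && violation <= tol_eff
  if (!converged) {
    warning(sprintf(
      "SVR solver did not reach tolerance %g (KKT violation %g after %d iterations)",
      tol, violation, it), call. = FALSE)
  }

  beta <- theta[1:n] - theta[(n + 1L):(2L * n)]
  # bias from free variables: b = -z_t G_t wherever 0 < theta_t < C
  slack <- 1e-8 * C
  free <- theta > slack & theta < C - slack
  up <- (z > 0 & theta < C) | (z < 0 & theta > 0)
  low <- (z > 0 & theta > 0) | (z < 0 & theta < C)
  nzG <- -z * G
  bias <- if (any(free)) {
    mean(nzG[free])
  } else {
    (max(nzG[up]) + min(nzG[low])) / 2
  }
  p_vec <- c(eps - y, eps + y)
  dual_objective <- 0.5 * sum(theta * (G - p_vec)) + sum(p_vec * theta)

  structure(
    list(dual_coefficients = beta,
         bias = bias,
         support_indices = which(abs(beta) > slack),
         converged = converged,
         iterations = it,
         kkt_violation = violation,
         dual_objective = dual_objective,
         clipped_mass = clipped_mass,
         config = config,
         n_train = n),
    class = "svr_model"
  )
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf(
    "<svr_model> %d training points, %d support vectors, bias %.4g\n",
    x$n_train, length(x$support_indices), x$bias))
  cat(sprintf("  C = %g, epsilon = %g, converged = %s (KKT violation %.2e)\n",
              x$config$cost, x$config$epsilon, x$converged, x$kkt_violation))
  if (x$clipped_mass > 0) {
    cat(sprintf("  indefinite Gram: clipped spectral mass %.3g\n",
                x$clipped_mass))
  }
  invisible(x)
}

#' Predict from a fitted SVR model given cross-kernel values
#'
#' @param model an `svr_model` from [fit_svr()].
#' @param gram_query matrix of kernel values K(train, query): one row per
#'   training point, one column per query point.
#' @return Numeric vector of predictions, one per query column.
#' @export
predict_svr <- function(model, gram_query) {
  stopifnot(inherits(model, "svr_model"))
  gram_query <- as.matrix(gram_query)
  if (nrow(gram_query) != model$n_train) {
    stop("gram_query must have one row per training point", call. = FALSE)
  }
  drop(crossprod(gram_query, model$dual_coefficients)) + model$bias
}

#' Fit a kernel SVR on raw descriptors with standardization
#'
#' High-level wrapper around [fit_svr()]: z-scores each descriptor by its
#' training mean and standard deviation (constant columns are left
#' unscaled), builds the training Gram under `spec`, solves the dual, and
#' stores everything needed to predict on new compounds. The kernel
#' length-scales are only meaningful on a fixed input scale, which is why
#' standardization lives here rather than inside the kernels.
#'
#' @param X training descriptor matrix.
#' @param y training response.
#' @param spec a [kernel_spec()].
#' @param config an [svr_config()].
#' @return An object of class `svr_fit`.
#' @export
svr_train <- function(X, y, spec, config = svr_config()) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  model <- fit_svr(gram_matrix(spec, Xs), y, config)
  structure(
    list(model = model, spec = spec,
         standardization = list(center = center, scale = scale),
         training_inputs = Xs),
    class = "svr_fit"
  )
}

#' @export
predict.svr_fit <- function(object, newdata, ...) {
  Xq <- as.matrix(newdata)
  Xq <- sweep(sweep(Xq, 2, object$standardization$center), 2,
              object$standardization$scale, "/")
  predict_svr(object$model, gram_matrix(object$spec, object$training_inputs, Xq))
}
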