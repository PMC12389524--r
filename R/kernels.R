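#' Kernel specification
#'
#' Describes one of the four kernels used by the SVR models:
#' \itemize{
#'   \item linear: \eqn{K(x, y) = x \cdot y}
#'   \item poly: \eqn{K(x, y) = (\gamma x \cdot y + r)^d}, \eqn{\gamma > 0}
#'   \item trig: \eqn{K(x, y) = \sin(\pi/2 + \sigma \|x - y\|^2)},
#'     \eqn{\sigma > 0}
#'   \item mixed: \eqn{\alpha K_{trig} + \beta K_{poly} +
#'     (1 - \alpha - \beta) K_{lin}} with \eqn{\alpha, \beta \in [0, 1]},
#'     \eqn{\alpha + \beta \le 1}
#' }
#' The distance in the trigonometric kernel is the squared Euclidean norm,
#' giving a unit diagonal (\eqn{K(x,x) = \sin(\pi/2) = 1}).
#'
#' @param family one of `"linear"`, `"poly"`, `"trig"`, `"mixed"`.
#' @param gamma polynomial coefficient \eqn{\gamma} (> 0 when the polynomial
#'   component is active).
#' @param offset polynomial offset \eqn{r}.
#' @param degree polynomial degree \eqn{d} (positive integer).
#' @param sigma trigonometric length-scale \eqn{\sigma} (> 0 when the
#'   trigonometric component is active).
#' @param weight_trig mixed-kernel weight \eqn{\alpha} in \[0, 1\].
#' @param weight_poly mixed-kernel weight \eqn{\beta} in \[0, 1\];
#'   the linear weight is \eqn{1 - \alpha - \beta \ge 0}.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("linear", "poly", "trig", "mixed"),
                        gamma = 1, offset = 0, degree = 3L, sigma = 1,
                        weight_trig = 0.5, weight_poly = 0.25) {
  family <- match.arg(family)
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be a positive integer", call. = FALSE)
  poly_active <- family == "poly" || (family == "mixed" && weight_poly > 0)
  trig_active <- family == "trig" || (family == "mixed" && weight_trig > 0)
  if (poly_active && gamma <= 0) {
    stop("gamma must be > 0 when the polynomial component is active",
         call. = FALSE)
  }
  if (trig_active && sigma <= 0) {
    stop("sigma must be > 0 when the trigonometric component is active",
         call. = FALSE)
  }
  if (family == "mixed") {
    if (weight_trig < 0 || weight_trig > 1 || weight_poly < 0 || weight_poly > 1) {
      stop("mixed-kernel weights must lie in [0, 1]", call. = FALSE)
    }
    if (weight_trig + weight_poly > 1 + 1e-12) {
      stop("mixed-kernel weights must satisfy weight_trig + weight_poly <= 1",
           call. = FALSE)
    }
  }
  structure(
    list(family = family, gamma = gamma, offset = offset, degree = degree,
         sigma = sigma, weight_trig = weight_trig, weight_poly = weight_poly),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> family = %s\n", x$family))
  if (x$family %in% c("poly", "mixed")) {
    cat(sprintf("  poly: gamma = %g, offset = %g, degree = %d\n",
                x$gamma, x$offset, x$degree))
  }
  if (x$family %in% c("trig", "mixed")) {
    cat(sprintf("  trig: sigma = %g\n", x$sigma))
  }
  if (x$family == "mixed") {
    cat(sprintf("  weights: trig = %g, poly = %g, linear = %g\n",
                x$weight_trig, x$weight_poly,
                1 - x$weight_trig - x$weight_poly))
  }
  invisible(x)
}

#' Evaluate a kernel on a single pair of vectors
#'
#' @param spec a [kernel_spec()].
#' @param x,y numeric vectors of equal length.
#' @return The scalar kernel value.
#' @export
kernel_eval <- function(spec, x, y) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(y)) {
    stop("kernel arguments must have the same length", call. = FALSE)
  }
  drop(gram_matrix(spec, matrix(x, 1), matrix(y, 1)))
}

#' Build a Gram (kernel) matrix
#'
#' Entry (i, j) is the kernel value between row i of `X` and row j of `Y`
#' (or of `X` when `Y` is missing, in which case the result is exactly
#' symmetric).
#'
#' @param spec a [kernel_spec()].
#' @param X numeric matrix (rows are points).
#' @param Y optional numeric matrix with the same column count as `X`.
#' @return The `nrow(X)` x `nrow(Y %||% X)` kernel matrix.
#' @export
gram_matrix <- function(spec, X, Y = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  X <- as.matrix(X)
  symmetric <- is.null(Y)
  Y <- if (symmetric) X else as.matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop("X and Y must have the same number of columns", call. = FALSE)
  }
  inner <- if (symmetric) tcrossprod(X) else tcrossprod(X, Y)
  lin <- function() inner
  pol <- function() (spec$gamma * inner + spec$offset)^spec$degree
  tri <- function() {
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * inner
    d2[d2 < 0] <- 0  # guard tiny negative round-off
    sin(pi / 2 + spec$sigma * d2)
  }
  switch(spec$family,
    linear = lin(),
    poly = pol(),
    trig = tri(),
    mixed = {
      a <- spec$weight_trig
      b <- spec$weight_poly
      G <- (1 - a - b) * lin()
      if (b > 0) G <- G + b * pol()
      if (a > 0) G <- G + a * tri()
      G
    }
  )
}
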