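# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# Euclidean projection onto {0 <= th <= C, z'th = 0} by bisection on the
# hyperplane multiplier.
project_box_hyperplane <- function(v, C, z) {
  f <- function(l) sum(z * pmin(pmax(v - l * z, 0), C))
  lo <- -max(abs(v)) - C - 1
  hi <- -lo
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  pmin(pmax(v - ((lo + hi) / 2) * z, 0), C)
}

# General-purpose accelerated projected-gradient (FISTA with monotone
# restart) solver for the epsilon-SVR dual QP in its 2n-variable form:
# min 0.5 th' Q th + p' th over the box-hyperplane set. Step 1/L with L the
# top eigenvalue of Q; stops when the objective stalls.
pg_svr_dual <- function(K, y, C, eps, max_iters = 100000L) {
  n <- length(y)
  z <- rep(c(1, -1), each = n)
  Q <- rbind(cbind(K, -K), cbind(-K, K))
  p <- c(eps - y, eps + y)
  L <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values) + 1e-9
  obj <- function(th) 0.5 * sum(th * drop(Q %*% th)) + sum(p * th)
  th <- rep(0, 2 * n)
  v <- th
  t_k <- 1
  f_best <- obj(th)
  f_checkpoint <- Inf
  for (k in seq_len(max_iters)) {
    G <- drop(Q %*% v) + p
    th_new <- project_box_hyperplane(v - G / L, C, z)
    if (obj(th_new) > f_best) {  # monotone restart from the best iterate
      v <- th
      t_k <- 1
      G <- drop(Q %*% v) + p
      th_new <- project_box_hyperplane(v - G / L, C, z)
    }
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    v <- th_new + ((t_k - 1) / t_new) * (th_new - th)
    th <- th_new
    t_k <- t_new
    f_best <- min(f_best, obj(th))
    if (k %% 500 == 0) {
      if (abs(f_checkpoint - f_best) <= 1e-12 * max(1, abs(f_best))) break
      f_checkpoint <- f_best
    }
  }
  beta <- th[1:n] - th[(n + 1):(2 * n)]
  list(theta = th, beta = beta, objective = obj(th), iterations = k)
}

# OLS via the normal equations (pseudoinverse), independent of lm/lm.fit.
normal_equations_ols <- function(X, y) {
  Xi <- cbind(1, X)
  s <- svd(Xi)
  pos <- s$d > max(s$d) * 1e-12
  drop(s$v[, pos, drop = FALSE] %*%
         ((t(s$u[, pos, drop = FALSE]) %*% y) / s$d[pos]))
}

# Shared small synthetic fixtures built in code.
linear_fixture <- function(seed = 1, n = 60, noise_sd = 0.2) {
  make_synthetic_dataset(synthetic_config(
    n_compounds = n, n_informative = 3, n_noise = 2, noise_sd = noise_sd,
    response_kind = "linear", coefficients = c(2, -1, 0.5), seed = seed))
}
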