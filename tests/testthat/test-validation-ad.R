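test_that("r_squared and rmse match their definitions", {
  y <- c(1, 2, 3, 5)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2))
  expect_error(r_squared(rep(1, 3), c(1, 2, 3)), "constant")
  # invariance of R^2 under a shared affine transform
  yhat <- c(1.1, 2.2, 2.7, 4.8)
  expect_equal(r_squared(2 * y - 3, 2 * yhat - 3), r_squared(y, yhat))
})

test_that("LOO Q^2 matches the closed form for the mean predictor", {
  ds <- linear_fixture(seed = 71, n = 15)
  mean_factory <- function(X, y) {
    m <- mean(y)
    function(Xnew) rep(m, nrow(as.matrix(Xnew)))
  }
  n <- 15
  # leaving i out, the train mean is (n*ybar - y_i)/(n-1), so the LOO
  # residual is (y_i - ybar) * n/(n-1) and Q^2 = 1 - (n/(n-1))^2
  expect_equal(q2_loo(mean_factory, ds$table), 1 - (n / (n - 1))^2,
               tolerance = 1e-12)
  # a perfect oracle gives exactly 1
  truth <- ds$table$response
  oracle_factory <- function(X, y) {
    function(Xnew) truth[match(apply(as.matrix(Xnew), 1, paste, collapse = ","),
                               apply(ds$table$descriptors, 1, paste,
                                     collapse = ","))]
  }
  expect_equal(q2_loo(oracle_factory, ds$table), 1)
  # OLS on noise-free linear data: exact model class
  ds0 <- linear_fixture(seed = 72, n = 30, noise_sd = 0)
  expect_equal(q2_loo(qsarmix:::ols_factory, ds0$table), 1, tolerance = 1e-8)
})

test_that("k-fold Q^2 is seeded and reduces to LOO at k = n", {
  ds <- linear_fixture(seed = 73, n = 10)
  fac <- qsarmix:::ols_factory
  expect_identical(q2_kfold(fac, ds$table, k = 5, seed = 2),
                   q2_kfold(fac, ds$table, k = 5, seed = 2))
  expect_equal(q2_kfold(fac, ds$table, k = 10, seed = 9),
               q2_loo(fac, ds$table), tolerance = 1e-14)
  failing_factory <- function(X, y) stop("boom")
  expect_error(q2_kfold(failing_factory, ds$table, k = 5), "fold 1")
})

test_that("Lin's CCC penalizes location and scale and is bounded by |r|", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  y <- c(1, 2, 3, 4)
  expect_lt(ccc(y, y + 2), 1)       # pure shift: CCC < Pearson r = 1
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(10)
    b <- rnorm(10) + 0.5 * a
    expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
  expect_error(ccc(rep(1, 3), rep(2, 3)), "undefined")
})

test_that("QF^2 external statistics follow their definitions", {
  expect_equal(qf_metrics(c(1, 2, 3), c(1, 2, 3), 7),
               c(qf1 = 1, qf2 = 1))
  # equal train and test means make the two denominators equal
  y_test <- c(0, 1, 2)
  yhat <- c(0.2, 0.9, 1.8)
  qf <- qf_metrics(y_test, yhat, mean(y_test))
  expect_equal(qf[["qf1"]], qf[["qf2"]])
  # hand-derived example
  expect_equal(qf_metrics(c(0, 1), c(0, 0), 0.5), c(qf1 = -1, qf2 = -1))
})

test_that("y-randomization destroys the fit but not the generator's seed", {
  ds <- make_synthetic_dataset(synthetic_config(
    n_compounds = 100, n_informative = 4, noise_sd = 0.1,
    response_kind = "linear", seed = 81))
  fac <- qsarmix:::ols_factory
  yr <- y_randomization(fac, ds$table, n_repeats = 10, seed = 5)
  expect_equal(nrow(yr), 10L)
  expect_identical(yr, y_randomization(fac, ds$table, n_repeats = 10, seed = 5))
  unpermuted <- r_squared(ds$table$response,
                          fac(ds$table$descriptors, ds$table$response)(
                            ds$table$descriptors))
  expect_gt(unpermuted, 0.9)
  expect_lt(attr(yr, "max_r2"), 0.3)
  # the mean predictor scores exactly zero under scrambling
  mean_factory <- function(X, y) {
    m <- mean(y)
    function(Xnew) rep(m, nrow(as.matrix(Xnew)))
  }
  yr0 <- y_randomization(mean_factory, ds$table[1:20], n_repeats = 3, seed = 1)
  expect_equal(yr0$r2_yrand, rep(0, 3))
})

test_that("leverages equal the hat-matrix diagonal and sum to p", {
  set.seed(91)
  X <- matrix(rnorm(30), 10, 3)
  h <- leverage(X)
  Xi <- cbind(1, X)
  H <- Xi %*% solve(crossprod(Xi)) %*% t(Xi)
  expect_equal(h, diag(H), tolerance = 1e-10)
  expect_equal(sum(h), 4, tolerance = 1e-8)
  # a single centered descriptor queried at the training mean: h = 1/n
  xc <- matrix(scale(rnorm(12), scale = FALSE), 12, 1)
  expect_equal(leverage(xc, matrix(mean(xc), 1, 1)), 1 / 12)
  expect_error(leverage(X, matrix(1, 2, 2)), "same columns")
})

test_that("Williams classification separates outliers from high leverage", {
  set.seed(92)
  n <- 40
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  # outside the training cloud (high leverage) but not so far that the
  # coefficient noise of the extrapolation exceeds the 3-sigma band
  X[n, ] <- c(5, -5)
  y <- X[, 1] + rnorm(n, sd = 0.3)
  tab <- descriptor_table(sprintf("c%02d", 1:n), X, y,
                          split_flag = c(rep("train", n - 1), "test"))
  fac <- qsarmix:::ols_factory
  pred <- fac(X[1:(n - 1), ], y[1:(n - 1)])(X)
  rep <- williams_report(tab, pred, p = 3)
  expect_equal(rep$h_star, 3 * 3 / (n - 1))
  expect_equal(sum(rep$compounds$leverage[tab$split_flag == "train"]), 3,
               tolerance = 1e-8)
  expect_equal(rep$compounds$classification[n], "influential")
  # verified against the explicit hat matrix on the training design
  Xi <- cbind(1, X[1:(n - 1), ])
  hi_oracle <- drop(cbind(1, X[n, , drop = FALSE]) %*%
                      solve(crossprod(Xi)) %*% t(cbind(1, X[n, , drop = FALSE])))
  expect_equal(rep$compounds$leverage[n], hi_oracle, tolerance = 1e-10)

  # all residuals zero except one: that row is the only response outlier
  # (its standardized residual is about sqrt(n), far beyond 3)
  tab2 <- descriptor_table(sprintf("c%02d", 1:n),
                           matrix(rnorm(n), n, 1, dimnames = list(NULL, "a")),
                           y, split_flag = rep("train", n))
  preds <- y
  preds[5] <- y[5] + 1
  rep2 <- williams_report(tab2, preds, p = 2)
  expect_equal(which(rep2$compounds$classification == "response_outlier"), 5L)
  expect_equal(sum(rep2$compounds$classification == "response_outlier"), 1L)
})

test_that("validation reports carry the conventional thresholds", {
  th <- validation_thresholds()
  expect_equal(unname(th[c("r2", "q2_loo", "q2_5fold", "ccc", "qf2")]),
               c(0.7, 0.6, 0.55, 0.85, 0.7))
  rep <- validation_report(r2_train = 0.95, rmse_train = 0.1,
                           r2_test = 0.65, rmse_test = 0.3,
                           q2_loo = 0.8, q2_5fold = 0.5, ccc = 0.9,
                           qf1 = 0.75, qf2 = 0.72)
  expect_true(rep$pass[["r2_train"]])
  expect_false(rep$pass[["r2_test"]])
  expect_false(rep$pass[["q2_5fold"]])
  expect_true(rep$pass[["ccc"]])
})
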