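test_that("single-channel PLS equals simple least squares", {
  set.seed(41)
  x <- rnorm(25); y <- 2 + 3 * x + rnorm(25, sd = 0.3)
  m <- fit_pls(matrix(x), y, 1)
  expect_equal(predict(m, matrix(x)), unname(fitted(lm(y ~ x))),
               tolerance = 1e-10)
})

test_that("full-rank PLS reproduces multiple-OLS predictions", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(15:40, 1); p <- sample(2:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- fit_pls(X, y, p)
    expect_equal(predict(m, X), unname(fitted(lm(y ~ X))),
                 tolerance = 1e-8)
  }
})

test_that("noiseless linear data is recovered exactly", {
  set.seed(43)
  X <- matrix(rnorm(20 * 3), 20, 3)
  y <- X %*% c(1, -2, 0.5)
  m <- fit_pls(X, as.numeric(y), 3)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
  # x_mean row predicts y_mean
  expect_equal(predict(m, matrix(m$x_mean, 1)), m$y_mean)
})

test_that("score-space and coefficient-space predictions agree", {
  set.seed(44)
  X <- matrix(rnorm(30 * 12), 30, 12); y <- rnorm(30)
  m <- fit_pls(X, y, 5)
  R <- m$weights %*% solve(crossprod(m$x_loadings, m$weights))
  T <- sweep(X, 2, m$x_mean) %*% R
  expect_equal(as.numeric(T %*% m$y_loadings) + m$y_mean, predict(m, X),
               tolerance = 1e-10)
  # successive score vectors orthogonal
  G <- crossprod(T)
  expect_equal(G, diag(diag(G)), tolerance = 1e-8)
})

test_that("fit_pls validates its inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(X, rnorm(10), 5), "n_lv")
  expect_error(fit_pls(X, rep(1, 10), 1), "zero-variance")
  Xn <- X; Xn[1] <- NA
  expect_error(fit_pls(Xn, rnorm(10), 1), "NaN")
  m <- fit_pls(X, rnorm(10), 2)
  expect_error(predict(m, matrix(1, 1, 3)), "channels")
})

test_that("rmse and r_squared follow their definitions", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  y <- rnorm(10); e <- rnorm(10)
  expect_equal(rmse(3 * y, 3 * (y + e)), 3 * rmse(y, y + e))
  expect_error(rmse(1:3, 1:4), "mismatch")
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 10)), 0)
  expect_lt(r_squared(y, -y), 0)     # worse than the mean predictor
  expect_error(r_squared(rep(2, 5), rnorm(5)), "constant")
  # identity linking the two metrics: R2 = 1 - n*rmse^2 / SS_tot
  yh <- y + e
  expect_equal(r_squared(y, yh),
               1 - 10 * rmse(y, yh)^2 / sum((y - mean(y))^2))
})

test_that("rmsecv pools repeats and matches the naive loop oracle", {
  set.seed(45)
  X <- matrix(rnorm(15 * 8), 15, 8); y <- rnorm(15)
  plan <- mccv_plan(7, 0.8, seed = 3)
  expect_equal(rmsecv(X, y, 2, plan),
               rmsecv_oracle(X, y, 2, mccv_splits(15, plan)),
               tolerance = 1e-10)
  # with a mask
  mask <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  expect_equal(rmsecv(X, y, 2, plan, mask),
               rmsecv_oracle(X, y, 2, mccv_splits(15, plan), mask),
               tolerance = 1e-10)
  # reproducible
  expect_identical(rmsecv(X, y, 2, plan), rmsecv(X, y, 2, plan))
  # noiseless linear data: essentially zero
  yl <- as.numeric(X %*% rnorm(8))
  expect_lt(rmsecv(X, yl, 8, plan), 1e-6)
  expect_error(rmsecv(X, y, 5, plan, mask = 1:3), "fewer channels")
})

test_that("latent-variable choice recovers a constructed low rank", {
  set.seed(46)
  n <- 40
  T2 <- matrix(rnorm(n * 2), n, 2)
  X <- T2 %*% matrix(rnorm(2 * 20), 2, 20)   # exact rank 2
  y <- as.numeric(T2 %*% c(1, -1))
  out <- select_lv_mccv(X, y, 6, mccv_plan(10, 0.8, seed = 8))
  expect_equal(out$n_lv, 2L)
  expect_lt(max(out$curve[2:6]), 1e-8)       # flat zero from rank on
  expect_length(out$curve, 6)
  # max_lv = 1 returns 1
  expect_equal(select_lv_mccv(X, y, 1, mccv_plan(5, 0.8, 1))$n_lv, 1L)
})
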