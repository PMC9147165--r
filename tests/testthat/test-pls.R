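test_that("one latent factor on one predictor equals simple regression", {
  set.seed(10)
  x <- rnorm(15)
  y <- 2 + 3 * x + rnorm(15, sd = 0.3)
  fit <- fit_pls1(matrix(x), y, k = 1)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(predict(fit, matrix(x)), unname(fitted(ols)), tolerance = 1e-10)
})

test_that("full-factor PLS1 matches least squares on random problems", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    q <- sample(2:min(8, n - 2), 1)
    X <- matrix(rnorm(n * q), n)
    y <- rnorm(n)
    fit <- fit_pls1(X, y, k = q)
    # oracle: least squares on centred data via QR
    Xc <- scale(X, scale = FALSE)
    beta <- qr.coef(qr(Xc), y - mean(y))
    pred_ls <- Xc %*% beta + mean(y)
    expect_equal(predict(fit, X), as.vector(pred_ls), tolerance = 1e-6)
  }
})

test_that("an uncorrelated response truncates to the zero regression vector", {
  # centred y orthogonal to every centred column: extraction stops at once
  X <- rbind(c(1, 2), c(1, 4), c(-1, 2), c(-1, 4))
  y <- c(0, 1, 1, 0) + 3
  Xc <- scale(X, scale = FALSE)
  stopifnot(max(abs(crossprod(Xc, y - mean(y)))) < 1e-12)
  fit <- fit_pls1(X, y, k = 2)
  expect_true(fit$truncated)
  expect_equal(fit$n_factors, 0L)
  expect_equal(fit$coefficients, c(0, 0))
  expect_equal(predict(fit, X), rep(mean(y), 4))
})

test_that("prediction is centred and exact on noiseless linear systems", {
  set.seed(12)
  X <- matrix(rnorm(12 * 4), 12)
  a <- c(1, -2, 0.5, 3)
  y <- as.vector(X %*% a) + 5
  fit <- fit_pls1(X, y, k = 4)
  expect_equal(predict(fit, X), y, tolerance = 1e-8)
  # the calibration mean row predicts the mean response
  expect_equal(predict(fit, matrix(fit$x_mean, 1)), fit$y_mean,
               tolerance = 1e-10)
  expect_error(predict(fit, matrix(1, 1, 3)), "columns")
})

test_that("invalid fits are rejected", {
  X <- matrix(rnorm(20), 10)
  expect_error(fit_pls1(X, rnorm(10), k = 0), "`k`")
  expect_error(fit_pls1(X, rnorm(10), k = 3), "`k`")  # k > q
  expect_error(fit_pls1(X, rep(1, 10), k = 1), "zero-variance")
})

test_that("scaling the response scales the model equivariantly", {
  set.seed(13)
  X <- matrix(rnorm(60), 12)
  y <- rnorm(12)
  f1 <- fit_pls1(X, y, k = 3)
  f2 <- fit_pls1(X, 10 * y, k = 3)
  expect_equal(f2$coefficients, 10 * f1$coefficients, tolerance = 1e-10)
  p1 <- predict(f1, X); p2 <- predict(f2, X)
  expect_equal(rmse(10 * y, p2), 10 * rmse(y, p1), tolerance = 1e-10)
  expect_equal(r_squared(10 * y, p2), r_squared(y, p1), tolerance = 1e-10)
})

test_that("calibration RMSE is non-increasing in the factor count", {
  set.seed(14)
  X <- matrix(rnorm(15 * 6), 15)
  y <- rnorm(15)
  errs <- vapply(1:6, function(k) {
    rmse(y, predict(fit_pls1(X, y, k = k), X))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("row-space reduction leaves PLS predictions unchanged", {
  set.seed(15)
  X <- matrix(rnorm(12 * 40), 12)   # q >> n
  y <- rnorm(12)
  Z <- oilspec:::reduce_rows(X)
  expect_lte(ncol(Z), 12)
  for (k in c(1, 3, 6)) {
    expect_equal(predict(fit_pls1(Z, y, k = k), Z),
                 predict(fit_pls1(X, y, k = k), X), tolerance = 1e-8)
  }
  # and the cross-validation path (which reduces internally) agrees with
  # an explicit fold-by-fold fit in the original feature space
  cv <- loocv_select(X, y, k_max = 4)
  direct <- vapply(1:4, function(k) {
    pr <- vapply(1:12, function(i) {
      predict(fit_pls1(X[-i, ], y[-i], k = k), X[i, , drop = FALSE])
    }, numeric(1))
    sqrt(mean((pr - y)^2))
  }, numeric(1))
  expect_equal(cv$rmsecv_by_k, direct, tolerance = 1e-8)
})

test_that("leave-one-sample-out finds a perfect univariate signal", {
  X <- matrix(seq(1, 12))
  y <- 2 * X[, 1] + 1
  cv <- loocv_select(X, y, k_max = 5)  # capped at q = 1
  expect_equal(cv$best_k, 1L)
  expect_lt(cv$rmsecv_by_k[1], 1e-8)
})

test_that("replicates held out together prevent leakage", {
  set.seed(17)
  X <- matrix(rnorm(12 * 5), 12)
  y <- rnorm(12)
  cv_sample <- loocv_select(X, y, k_max = 4)
  X3 <- X[rep(1:12, each = 3), ]
  y3 <- y[rep(1:12, each = 3)]
  cv_grouped <- loocv_select(X3, y3, k_max = 4, groups = rep(1:12, each = 3))
  # exact replicate rows held out together reproduce the sample-level CV
  expect_equal(cv_grouped$rmsecv_by_k, cv_sample$rmsecv_by_k, tolerance = 1e-8)
  # leaving single rows out lets replicates leak: error cannot be larger
  cv_leaky <- loocv_select(X3, y3, k_max = 4)
  expect_lte(min(cv_leaky$rmsecv_by_k), min(cv_grouped$rmsecv_by_k) + 1e-8)
})

test_that("cross-validated error on pure noise stays near the noise level", {
  set.seed(18)
  frac_ok <- mean(vapply(1:50, function(i) {
    X <- matrix(rnorm(12 * 8), 12)
    y <- rnorm(12)
    cv <- loocv_select(X, y, k_max = 6)
    cv$rmsecv_by_k[cv$best_k] >= 0.5 * sd(y)
  }, logical(1)))
  expect_gte(frac_ok, 0.9)
})

test_that("quality metrics follow their definitions", {
  y <- c(1, 2, 3, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_lt(r_squared(y, c(4, 3, 2, 1)), 0)  # worse than the mean predictor
  expect_error(r_squared(rep(1, 3), rep(1, 3)), "variance")
  expect_equal(rmse(c(1, -1), c(0, 0)), 1)
  expect_equal(rmse(3, 0), 3)
  expect_equal(rmse(y, y), 0)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("models serialize to flat text and predict identically", {
  set.seed(19)
  X <- matrix(rnorm(40), 10)
  y <- rnorm(10)
  fit <- fit_pls1(X, y, k = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_pls1(fit, path)
  back <- read_pls1(path)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
  expect_equal(back$n_factors, fit$n_factors)
})

test_that("tidy and glance expose the fit as tibbles", {
  set.seed(20)
  f <- features(matrix(rnorm(50), 10), axis = seq(600, by = 4, length.out = 5))
  y <- rnorm(10)
  fit <- fit_pls1(f, y, k = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  expect_equal(td$wavenumber, f$axis)
  gl <- glance(fit)
  expect_equal(gl$n_factors, 2L)
  cv <- loocv_select(f, y, k_max = 3)
  expect_equal(nrow(tidy(cv)), 3)
})
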