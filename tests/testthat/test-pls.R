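test_that("noiseless linear data is recovered exactly at full rank", {
  beta <- c(1.5, -2, 0.7)
  prob <- make_regression(30, beta, sigma = 0, seed = 2)
  df <- tibble::as_tibble(as.data.frame(prob$X)); df$activity <- prob$y
  fit <- fit_qsar(df, descriptors = colnames(prob$X), n_latent = 3)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
  expect_equal(fit$r2_train, 1, tolerance = 1e-10)
  expect_lt(fit$rmse_train, 1e-8)
})

test_that("single-descriptor PLS equals ordinary least squares", {
  set.seed(9)
  x <- rnorm(40); y <- 2 + 3 * x + rnorm(40, 0, 0.5)
  df <- tibble::tibble(x1 = x, activity = y)
  fit <- fit_qsar(df, descriptors = "x1", n_latent = 1)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)[2]),
               tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
})

test_that("PLS predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(21)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  X[, 4] <- X[, 1] * 0.8 + rnorm(n, 0, 0.3)     # some collinearity
  y <- X %*% c(1, -0.5, 0.25, 0.8) + rnorm(n, 0, 0.4)
  for (nc in 1:3) {
    mine <- pls1_fit(X, as.vector(y), nc, scale = TRUE)
    mo <- mixOmics::pls(X, as.vector(y), ncomp = nc, scale = TRUE,
                        mode = "regression")
    pred_mo <- predict(mo, X)$predict[, 1, nc]
    expect_equal(unname(mine$fitted), unname(pred_mo), tolerance = 1e-6)
  }
})

test_that("planted coefficients are recovered from noisy simulations", {
  beta <- c(0.8, 1.2, -0.6, -0.9, 1.1)
  ok_sign <- 0; ok_err <- 0
  for (seed in 1:50) {
    prob <- make_regression(67, beta, sigma = 0.3, seed = seed)
    fit <- pls1_fit(prob$X, prob$y, 5)
    b <- unname(fit$coefficients)
    if (all(sign(b) == sign(beta))) ok_sign <- ok_sign + 1
    if (max(abs(b - beta) / abs(beta)) <= 0.2) ok_err <- ok_err + 1
  }
  expect_equal(ok_sign, 50)
  expect_gte(ok_err, 45)
})

test_that("leave-one-out scoring matches an lm-based oracle at full rank", {
  set.seed(5)
  n <- 25
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- X %*% c(1, -1, 0.5) + rnorm(n, 0, 0.6)
  press <- 0
  for (i in seq_len(n)) {
    d <- data.frame(y = y[-i], X[-i, ])
    m <- lm(y ~ ., data = d)
    pred <- predict(m, newdata = as.data.frame(X)[i, , drop = FALSE])
    press <- press + (y[i] - pred)^2
  }
  oracle <- 1 - press / sum((y - mean(y))^2)
  expect_equal(loo_xr2(X, as.vector(y), 3), unname(oracle), tolerance = 1e-8)
})

test_that("xr2 behaves like a cross-validation statistic", {
  # perfectly linear noiseless data scores 1
  prob <- make_regression(20, c(1, 2), sigma = 0, seed = 4)
  expect_equal(loo_xr2(prob$X, prob$y, 2), 1, tolerance = 1e-8)
  # pure-noise responses score at or below zero on average
  set.seed(77)
  scores <- replicate(100, {
    X <- matrix(rnorm(20 * 2), 20, 2)
    loo_xr2(X, rnorm(20), 1)
  })
  expect_lt(mean(scores), 0)
  # xr2 never beats the training r2 at matched latent count
  for (seed in 1:20) {
    prob <- make_regression(30, c(1, -0.5, 0.3), sigma = 0.5,
                            seed = seed + 300)
    df <- tibble::as_tibble(as.data.frame(prob$X)); df$activity <- prob$y
    fit <- fit_qsar(df, descriptors = colnames(prob$X), n_latent = 3)
    expect_lte(fit$xr2_loo, fit$r2_train + 1e-10)
  }
})

test_that("degenerate inputs are rejected or repaired", {
  df <- tibble::tibble(x1 = rnorm(20), x2 = 1, activity = rnorm(20))
  expect_warning(fit <- fit_qsar(df, descriptors = c("x1", "x2")),
                 "zero-variance")
  expect_identical(fit$descriptors, "x1")
  df2 <- tibble::tibble(x1 = rnorm(20), activity = 5)
  expect_error(suppressWarnings(fit_qsar(df2, descriptors = "x1")), "constant")
})
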