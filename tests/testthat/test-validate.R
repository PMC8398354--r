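# a minimal hand-built model whose prediction is just the x1 column
identity_model <- function() {
  structure(list(descriptors = "x1", coefficients = c(x1 = 1), intercept = 0),
            class = "qsar_model")
}

test_that("perfect predictions score r2 = 1, RMSE = 0", {
  df <- tibble::tibble(id = as.character(1:10), x1 = seq(6, 9, length.out = 10))
  df$activity <- df$x1
  v <- validate_qsar(identity_model(), df)
  expect_equal(v$metrics$r2, 1, tolerance = 1e-12)
  expect_equal(v$metrics$rmse, 0, tolerance = 1e-12)
  expect_equal(v$metrics$n_outliers, 0)
})

test_that("a constant offset moves RMSE but not the correlation r2", {
  set.seed(8)
  x <- rnorm(20, 7.5, 0.8)
  base <- tibble::tibble(id = as.character(1:20), x1 = x,
                         activity = x + rnorm(20, 0, 0.3))
  v0 <- validate_qsar(identity_model(), base)
  for (delta in c(0.5, 1.4)) {
    shifted <- base
    shifted$activity <- base$activity - delta
    v <- validate_qsar(identity_model(), shifted)
    expect_equal(v$metrics$r2, v0$metrics$r2, tolerance = 1e-12)
  }
  # exact-offset case: residuals all delta
  exact <- tibble::tibble(id = as.character(1:20), x1 = x, activity = x - 0.7)
  v <- validate_qsar(identity_model(), exact)
  expect_equal(v$metrics$rmse, 0.7, tolerance = 1e-12)
})

test_that("dropping the two worst molecules lowers the RMSE", {
  set.seed(12)
  df <- tibble::tibble(id = as.character(1:20), x1 = rnorm(20, 7.5, 0.8))
  df$activity <- df$x1 + rnorm(20, 0, 0.4)
  v <- validate_qsar(identity_model(), df)
  res <- tidy(v)
  worst <- res$id[order(abs(res$residual), decreasing = TRUE)][1:2]
  v2 <- validate_qsar(identity_model(), dplyr::filter(df, !.data$id %in% worst))
  expect_lt(v2$metrics$rmse, v$metrics$rmse)
})

test_that("outliers are flagged through the validation report", {
  df <- tibble::tibble(id = c("a", "b", "c"), x1 = c(7, 7, 7),
                       activity = c(7.1, 4.2, 6.9))
  v <- validate_qsar(identity_model(), df)
  expect_equal(v$metrics$n_outliers, 1)
  expect_identical(tidy(v)$id[tidy(v)$outlier], "b")
  expect_error(validate_qsar(identity_model(), df[0, ]), "empty")
})

test_that("applicability domain follows the average-similarity cutoff", {
  ref <- tibble::tibble(id = sprintf("bzd%02d", 1:10), smiles = BZD_TEN)
  # a member of the reference set is in-domain
  q1 <- applicability_domain(ref[1, ], ref)
  expect_true(q1$in_domain)
  expect_gte(q1$avg_tc, 0.5)
  # hexane is far outside
  q2 <- applicability_domain(tibble::tibble(id = "hexane", smiles = HEXANE), ref)
  expect_false(q2$in_domain)
  expect_lt(q2$avg_tc, 0.2)
  # cutoff 0 admits everything
  q3 <- applicability_domain(tibble::tibble(id = "hexane", smiles = HEXANE),
                             ref, cutoff = 0)
  expect_true(q3$in_domain)
  expect_error(applicability_domain(ref, ref[0, ]), "empty")
})
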