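test_that("the published equation evaluates exactly as printed", {
  zero <- c(h_log_pbo = 0, kier_flex = 0, q_vsa_hyd = 0,
            slogp_vsa7 = 0, vsa_pol = 0)
  expect_identical(predict_published(zero), 9.45416)
  one_hlp <- zero; one_hlp["h_log_pbo"] <- 1
  expect_equal(predict_published(one_hlp), 9.45416 + 0.77505,
               tolerance = 1e-12)
})

test_that("the equation is exactly affine in every descriptor", {
  pm <- published_model()
  zero <- setNames(numeric(5), names(pm$coefficients))
  base <- predict_published(zero)
  for (nm in names(pm$coefficients)) {
    for (h in c(1, 2.5, -3)) {
      v <- zero; v[nm] <- h
      expect_equal(predict_published(v) - base, pm$coefficients[[nm]] * h,
                   tolerance = 1e-12)
    }
  }
})

test_that("data-frame predictions append .pred", {
  df <- tibble::tibble(h_log_pbo = c(0, 1), kier_flex = 0, q_vsa_hyd = 0,
                       slogp_vsa7 = 0, vsa_pol = c(0, 1))
  out <- predict_published(df)
  expect_equal(out$.pred, c(9.45416, 9.45416 + 0.77505 - 0.03849),
               tolerance = 1e-12)
})

test_that("potency bins follow the printed half-open intervals", {
  expect_equal(as.character(bin_activity(8.61)), "high")     # phenazepam
  expect_equal(as.character(bin_activity(7.50)), "medium")   # diazepam
  expect_equal(as.character(bin_activity(c(6.99, 7.00, 7.99, 8.00, 5.80))),
               c("low", "medium", "medium", "high", "low"))
  expect_warning(b <- bin_activity(5.79), "outside")
  expect_equal(as.character(b), "out_of_range")
  expect_error(bin_activity(NaN), "finite")
})

test_that("outlier flagging uses a strict 2.5-unit rule", {
  expect_false(flag_outliers(7, 9.5))            # exactly 2.5: not flagged
  expect_true(flag_outliers(7, 9.6))
  expect_true(flag_outliers(7, 10))              # deviation 3.0
  expect_equal(flag_outliers(c(7, 7, 7), c(7.1, 9.6, 8.0)),
               c(FALSE, TRUE, FALSE))
  # under-prediction is caught by default but not in "over" mode
  expect_true(flag_outliers(7, 4.4))
  expect_false(flag_outliers(7, 4.4, direction = "over"))
  expect_true(flag_outliers(7, 9.6, direction = "over"))
})
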