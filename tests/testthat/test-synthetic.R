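test_that("library generation is a pure function of its seed", {
  a <- generate_library(15, seed = 3, mode = "screen")
  b <- generate_library(15, seed = 3, mode = "screen")
  expect_identical(a$smiles, b$smiles)
  expect_identical(a$activity_true, b$activity_true)
  c <- generate_library(15, seed = 4, mode = "screen")
  expect_false(identical(a$smiles, c$smiles))
  expect_false(any(duplicated(a$smiles)))
})

test_that("requests beyond the enumerable space are rejected", {
  expect_error(generate_library(10000, seed = 1, mode = "screen"),
               "at most")
})

test_that("planted activities follow the published equation exactly at sigma 0", {
  lib <- generate_library(12, seed = 6, mode = "screen")
  lib0 <- assign_activities(lib, sigma = 0, seed = 1)
  expect_equal(lib0$activity, lib0$activity_true, tolerance = 1e-12)
  fx <- featurize(lib0)
  pred <- predict_published(fx)$.pred
  expect_equal(pred, lib0$activity, tolerance = 1e-9)
})

test_that("noise has the configured spread and its own seed", {
  lib <- generate_library(76, seed = 2, mode = "screen")
  noisy <- assign_activities(lib, sigma = 0.3, seed = 5, activity_range = NULL)
  resid <- noisy$activity - noisy$activity_true
  expect_gt(sd(resid), 0.3 * 0.7)
  expect_lt(sd(resid), 0.3 * 1.3)
  again <- assign_activities(lib, sigma = 0.3, seed = 5, activity_range = NULL)
  expect_identical(noisy$activity, again$activity)
  other <- assign_activities(lib, sigma = 0.3, seed = 6, activity_range = NULL)
  expect_false(identical(noisy$activity, other$activity))
  expect_error(assign_activities(lib, sigma = -1), "non-negative")
})

test_that("range handling keeps the activity span literal", {
  lib <- generate_library(40, seed = 9, mode = "screen",
                          activity_range = c(6, 9))
  expect_true(all(lib$activity_true >= 6 & lib$activity_true <= 9))
  noisy <- assign_activities(lib, sigma = 0.4, seed = 2,
                             activity_range = c(6, 9))
  expect_true(all(noisy$activity >= 6 & noisy$activity <= 9))
})

test_that("the manifest regenerates the library exactly", {
  lib <- bzd_library(20, seed = 13, sigma = 0.2, mode = "screen",
                     activity_range = c(6, 9))
  m <- attr(lib, "manifest")
  expect_equal(m$n, 20)
  replay <- bzd_library(m$n, seed = m$seed, sigma = m$sigma, mode = m$mode,
                        activity_range = unlist(m$activity_range))
  expect_identical(lib$smiles, replay$smiles)
  expect_identical(lib$activity, replay$activity)
})

test_that("datasets round-trip through disk losslessly", {
  lib <- bzd_library(10, seed = 21, sigma = 0.1, mode = "screen",
                     activity_range = NULL)
  path <- file.path(tempdir(), "synlib")
  files <- write_dataset(lib, path)
  expect_identical(readLines(files["csv"], n = 1), "id,smiles,activity")
  back <- read_dataset(path)
  expect_identical(back$id, lib$id)
  expect_identical(back$smiles, lib$smiles)
  expect_equal(back$activity, lib$activity, tolerance = 1e-12)
  expect_equal(attr(back, "manifest")$seed, 21)
})

test_that("generated molecules parse and survive curation", {
  # train-mode congener libraries: the curation premise of the workflow
  for (seed in 1:3) {
    lib <- generate_library(20, seed = seed, anneal_iters = 2000L)
    fx <- featurize(lib)
    expect_equal(nrow(fx), 20)
    kept <- curate(fx)
    expect_gte(nrow(kept) / nrow(fx), 0.95)
  }
  # screen-mode libraries at least all parse
  for (seed in 4:5) {
    lib <- generate_library(25, seed = seed, mode = "screen")
    expect_equal(nrow(featurize(lib)), 25)
  }
})
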