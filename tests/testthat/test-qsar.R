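# helper: orthonormal mean-zero basis so constructed correlations are exact
orthobasis <- function(n, k, seed = 1) {
  set.seed(seed)
  M <- scale(matrix(rnorm(n * (k + 2)), n), center = TRUE, scale = FALSE)
  qr.Q(qr(M))[, seq_len(k), drop = FALSE]
}

test_that("curation keeps congeners and removes structural strays", {
  same <- tibble::tibble(id = as.character(1:5),
                         smiles = rep(DIAZEPAM, 5))
  out <- curate(same)
  expect_equal(nrow(out), 5)
  expect_equal(out$avg_tc, rep(1, 5))

  mixed <- tibble::tibble(id = c(sprintf("bzd%02d", 1:10), "alkane"),
                          smiles = c(BZD_TEN, "CCCCCCCCCCCC"))
  expect_message(kept <- curate(mixed), "removed")
  expect_false("alkane" %in% kept$id)
  expect_equal(nrow(kept), 10)
  removed <- attr(kept, "removed")
  expect_equal(removed$id, "alkane")
  expect_lt(removed$avg_tc, 0.3)
})

test_that("split respects the 80/20 arithmetic and is seed-deterministic", {
  lib <- data.frame(id = as.character(1:76), smiles = DIAZEPAM,
                    activity = seq(6, 9, length.out = 76),
                    avg_tc = rep(0.8, 76))
  s1 <- split_dataset(lib, seed = 11)
  expect_setequal(s1$set, c("train", "test"))
  expect_true(abs(sum(s1$set == "test") - 15) <= 1)
  s2 <- split_dataset(lib, seed = 11)
  expect_identical(s1$set, s2$set)
  s3 <- split_dataset(lib, seed = 12)
  expect_false(identical(s1$set, s3$set))
})

test_that("test activities lie inside the training range", {
  lib <- data.frame(id = as.character(1:40), smiles = DIAZEPAM,
                    avg_tc = rep(0.8, 40))
  for (seed in 1:25) {
    set.seed(seed + 500)
    lib$activity <- runif(40, 6, 9)
    sp <- suppressWarnings(split_dataset(lib, seed = seed))
    tr <- sp$activity[sp$set == "train"]
    te <- sp$activity[sp$set == "test"]
    expect_gte(min(te), min(tr))
    expect_lte(max(te), max(tr))
  }
})

test_that("selection traces the two published filters", {
  B <- orthobasis(200, 4, seed = 7)
  y <- B[, 1]
  d1 <- 0.9 * B[, 1] + sqrt(1 - 0.81) * B[, 2]
  b2 <- (0.8 - 0.9 * 0.6) / sqrt(1 - 0.81)
  d2 <- 0.6 * B[, 1] + b2 * B[, 2] + sqrt(1 - 0.36 - b2^2) * B[, 3]
  d3 <- 0.2 * B[, 1] + sqrt(1 - 0.04) * B[, 4]
  df <- tibble::tibble(activity = y, d1 = d1, d2 = d2, d3 = d3)
  # construction check: r(y,d1)=0.9, r(y,d2)=0.6, r(y,d3)=0.2, r(d1,d2)=0.8
  expect_equal(cor(df$d1, df$activity), 0.9, tolerance = 1e-10)
  expect_equal(cor(df$d1, df$d2), 0.8, tolerance = 1e-10)
  sel <- select_descriptors(df, descriptors = c("d1", "d2", "d3"))
  expect_identical(sel$selected, "d1")
  rep <- sel$report
  expect_match(rep$reason[rep$descriptor == "d2"], "collinear")
  expect_match(rep$reason[rep$descriptor == "d3"], "< 0.50")
})

test_that("perfect and duplicate descriptors are handled", {
  set.seed(3)
  y <- rnorm(50)
  df <- tibble::tibble(activity = y, exact = y, dup1 = y + rnorm(50, 0, 0.1))
  df$dup2 <- df$dup1
  sel <- select_descriptors(df, descriptors = c("exact", "dup1", "dup2"))
  expect_true("exact" %in% sel$selected)
  expect_equal(sum(c("dup1", "dup2") %in% sel$selected), 0)  # collinear with exact
  # nothing survives -> informative rejection
  noise <- tibble::tibble(activity = rnorm(50), a = rnorm(50), b = rnorm(50))
  expect_error(select_descriptors(noise, descriptors = c("a", "b")),
               "no descriptor survives")
})

test_that("no surviving pair is collinear, across seeded random problems", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 60
    base <- matrix(rnorm(n * 3), n)
    X <- cbind(base,
               base[, 1] + rnorm(n, 0, 0.2),    # near-duplicate
               base[, 2] * 0.9 + rnorm(n, 0, 0.3))
    colnames(X) <- paste0("v", 1:5)
    y <- base %*% c(1, 0.8, 0.5) + rnorm(n, 0, 0.4)
    df <- tibble::as_tibble(as.data.frame(X))
    df$activity <- as.vector(y)
    sel <- tryCatch(select_descriptors(df, descriptors = colnames(X)),
                    error = function(e) NULL)
    if (is.null(sel) || length(sel$selected) < 2) next
    cm <- cor(df[, sel$selected])
    expect_lte(max(abs(cm[upper.tri(cm)])), 0.7)
  }
})
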