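test_that("tanimoto follows set algebra on constructed bit sets", {
  expect_equal(tanimoto(make_fp(1:10), make_fp(1:10)), 1.0)
  expect_equal(tanimoto(make_fp(1:5), make_fp(6:10)), 0.0)
  expect_equal(tanimoto(make_fp(c(1, 2, 3)), make_fp(c(2, 3, 4))), 0.5)
  expect_error(tanimoto(make_fp(1, nbits = 1024), make_fp(1, nbits = 2048)),
               "length")
  expect_warning(z <- tanimoto(make_fp(integer(0)), make_fp(integer(0))),
                 "empty")
  expect_equal(z, 0)
})

test_that("tanimoto is symmetric, bounded and 1 iff identical", {
  set.seed(42)
  for (i in 1:20) {
    a <- make_fp(sample(0:2047, sample(5:60, 1)))
    b <- make_fp(sample(0:2047, sample(5:60, 1)))
    t1 <- tanimoto(a, b)
    expect_identical(t1, tanimoto(b, a))
    expect_gte(t1, 0); expect_lte(t1, 1)
    if (t1 == 1) expect_identical(unclass(a), unclass(b))
  }
})

test_that("molecular fingerprints separate molecules and are non-empty", {
  f_eth <- fingerprint("CC")
  f_benz <- fingerprint("c1ccccc1")
  expect_gte(length(f_eth), 1)
  expect_gte(length(fingerprint("[Br-]")), 1)   # single-atom molecule
  expect_lt(tanimoto(f_eth, f_benz), 1)
})

test_that("fingerprints and descriptors are invariant to SMILES spelling", {
  spellings <- list(
    diazepam = c(
      "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21",
      "O=C1CN=C(c2ccccc2)c2cc(Cl)ccc2N1C",
      "Clc1ccc2c(c1)C(=NCC(=O)N2C)c1ccccc1",
      "c1ccc(cc1)C1=NCC(=O)N(C)c2ccc(Cl)cc12",
      "N1(C)C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21"
    ),
    toluene = c("Cc1ccccc1", "c1ccccc1C", "c1ccc(C)cc1",
                "C1=CC=CC=C1C", "c1cc(C)ccc1")
  )
  for (sp in spellings) {
    fps <- lapply(sp, fingerprint)
    descs <- lapply(sp, compute_descriptors)
    for (k in seq_along(sp)[-1]) {
      expect_identical(unclass(fps[[k]]), unclass(fps[[1]]))
      expect_equal(descs[[k]], descs[[1]], tolerance = 1e-12)
    }
  }
})

test_that("average_tc is the arithmetic mean excluding self", {
  t <- make_fp(1:10)
  expect_equal(average_tc(t, list(t, t, t)), 1.0)
  expect_equal(average_tc(t, list(make_fp(100:110), make_fp(200:210))), 0)
  # pairwise similarities 0.6 and 0.2 by construction
  a <- make_fp(c(1:6, 90, 91, 92, 93))          # |a n t| = 6, union = 14
  expect_equal(tanimoto(t, make_fp(1:6)), 0.6)
  b <- make_fp(c(1, 2, 3, 11:15))               # 3 / 15
  expect_equal(tanimoto(t, b), 0.2)
  expect_equal(average_tc(t, list(make_fp(1:6), b)), 0.4)
  expect_error(average_tc(t, list(t)), "empty")
})
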