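test_that("simple molecules parse to the expected graphs", {
  eth <- parse_smiles("CC")
  expect_equal(nrow(eth$atoms), 2)
  expect_equal(nrow(eth$bonds), 1)
  expect_equal(eth$atoms$nH, c(3L, 3L))

  benz <- parse_smiles("c1ccccc1")
  expect_equal(nrow(benz$atoms), 6)
  expect_true(all(benz$atoms$aromatic))
  expect_equal(sum(benz$bonds$aromatic), 6)

  dz <- parse_smiles(DIAZEPAM)
  expect_equal(nrow(dz$atoms), 20)   # C16 H13 Cl N2 O
  expect_equal(sum(dz$atoms$element == "Cl"), 1)
})

test_that("kekulised input is re-aromatised consistently", {
  a <- parse_smiles("C1=CC=CC=C1")
  b <- parse_smiles("c1ccccc1")
  expect_identical(a$smiles, b$smiles)
  expect_true(all(a$atoms$aromatic))
})

test_that("heteroaromatic perception covers the scaffold chemistry", {
  pyr <- parse_smiles("c1ccncc1")            # pyridine
  expect_true(all(pyr$atoms$aromatic))
  expect_equal(pyr$atoms$nH[pyr$atoms$element == "N"], 0L)

  pyrrole <- parse_smiles("c1cc[nH]c1")
  expect_true(all(pyrrole$atoms$aromatic))
  expect_equal(pyrrole$atoms$nH[pyrrole$atoms$element == "N"], 1L)

  thio <- parse_smiles("c1ccsc1")            # thiophene
  expect_true(all(thio$atoms$aromatic))

  chx <- parse_smiles("C1CCCCC1")            # cyclohexane: not aromatic
  expect_false(any(chx$atoms$aromatic))

  dz <- parse_smiles(DIAZEPAM)               # 7-ring stays non-aromatic
  expect_equal(sum(dz$atoms$aromatic), 12)
})

test_that("formal charges and implicit hydrogens follow valence rules", {
  nb <- parse_smiles("c1ccc(cc1)[N+](=O)[O-]")   # nitrobenzene
  n_idx <- which(nb$atoms$element == "N")
  o_minus <- which(nb$atoms$charge == -1)
  expect_equal(nb$atoms$charge[n_idx], 1L)
  expect_length(o_minus, 1)
  expect_equal(nb$atoms$nH[n_idx], 0L)
  expect_equal(sum(nb$atoms$charge), 0L)
})

test_that("largest covalent fragment is kept", {
  salt <- parse_smiles("CCN.Cl")
  expect_equal(nrow(salt$atoms), 3)
  expect_false("Cl" %in% salt$atoms$element)
})

test_that("canonicalisation is idempotent and spelling-independent", {
  can1 <- canonical_smiles(DIAZEPAM)
  can2 <- canonical_smiles(can1)
  expect_identical(can1, can2)
  expect_identical(canonical_smiles("OCC"), canonical_smiles("CCO"))
})

test_that("parse failures are informative", {
  expect_error(parse_smiles(""), "empty")
  expect_error(parse_smiles("CC(("), "position")
  expect_error(parse_smiles("C!!C"), "invalid character")
})
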