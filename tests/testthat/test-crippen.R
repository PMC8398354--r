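test_that("aliphatic and aromatic carbons get the published classes", {
  hex <- crippen_contribs(parse_smiles(HEXANE))
  expect_true(all(hex$type %in% c("C1", "C2")))

  benz <- crippen_contribs(parse_smiles("c1ccccc1"))
  expect_true(all(benz$type == "C18"))
  expect_equal(length(unique(benz$contrib)), 1)

  # chlorobenzene: one halogen-bearing aromatic carbon, one chlorine
  cb <- parse_smiles("Clc1ccccc1")
  tc <- crippen_contribs(cb)
  expect_equal(sum(tc$type == "C15"), 1)
  expect_equal(sum(tc$type == "Cl"), 1)
  expect_equal(sum(tc$type == "C18"), 5)
})

test_that("functional-group classes match the published table", {
  # acetamide: carbonyl C5, amide N1, carbonyl O9 family
  am <- parse_smiles("CC(=O)N")
  tam <- crippen_contribs(am)
  expect_true("C5" %in% tam$type)
  expect_equal(tam$type[am$atoms$element == "O"], "O9")
  # aniline N3; pyridine N11; nitro N13
  expect_true("N3" %in% crippen_contribs(parse_smiles("Nc1ccccc1"))$type)
  expect_true("N11" %in% crippen_contribs(parse_smiles("c1ccncc1"))$type)
  expect_true("N13" %in%
                crippen_contribs(parse_smiles("c1ccc(cc1)[N+](=O)[O-]"))$type)
  # hydroxyl O2, ether O3, aromatic attachment O4
  expect_true("O2" %in% crippen_contribs(parse_smiles("CCO"))$type)
  expect_true("O3" %in% crippen_contribs(parse_smiles("COC"))$type)
  expect_true("O4" %in% crippen_contribs(parse_smiles("COc1ccccc1"))$type)
})

test_that("contributions sum to a sane molecular logP", {
  # benzene: 6 aromatic CH = 6 * (0.1581 + 0.123) = 1.6866
  tb <- crippen_contribs(parse_smiles("c1ccccc1"))
  expect_equal(sum(tb$contrib), 6 * (0.1581 + 0.123), tolerance = 1e-10)
  # hexane: 2 CH3 + 4 CH2 carbons, 14 H1 hydrogens
  th <- crippen_contribs(parse_smiles(HEXANE))
  expect_equal(sum(th$contrib), 6 * 0.1441 + 14 * 0.123, tolerance = 1e-10)
})

test_that("every heavy atom gets exactly one class", {
  for (smi in BZD_TEN) {
    tc <- crippen_contribs(parse_smiles(smi))
    expect_false(any(is.na(tc$logp)))
  }
})
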