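test_that("an unbonded atom gets its full sphere", {
  br <- parse_smiles("[Br-]")
  expect_equal(atom_vsa(br), 4 * pi * 2.166^2, tolerance = 1e-10)
})

test_that("symmetry and cap subtraction behave as the closed form dictates", {
  eth <- parse_smiles("CC")
  v_eth <- atom_vsa(eth)
  expect_equal(v_eth[1], v_eth[2], tolerance = 1e-10)

  met <- parse_smiles("C")
  v_met <- atom_vsa(met)
  # methane's carbon trades one C cap for an H cap; independent computation
  # of the difference from the cap-area formula
  cap <- function(R, r, d) 2 * pi * R * (R - d / 2 - (R^2 - r^2) / (2 * d))
  rC <- 1.950; rH <- 1.485; dCC <- 1.54; dCH <- 1.09
  # heavy-atom sphere part
  heavy_met <- 4 * pi * rC^2 - 4 * cap(rC, rH, dCH)
  heavy_eth <- 4 * pi * rC^2 - cap(rC, rC, dCC) - 3 * cap(rC, rH, dCH)
  h_piece <- 4 * pi * rH^2 - cap(rH, rC, dCH)
  expect_equal(v_met[1], heavy_met + 4 * h_piece, tolerance = 1e-8)
  expect_equal(v_eth[1], heavy_eth + 3 * h_piece, tolerance = 1e-8)
  expect_gt(v_met[1], v_eth[1])
})

test_that("per-atom areas are non-negative across the library chemistry", {
  for (smi in BZD_TEN) expect_true(all(atom_vsa(parse_smiles(smi)) >= 0))
})

test_that("SlogP_VSA bins and charge partition conserve total VSA", {
  mols <- c(BZD_TEN, HEXANE, "c1ccccc1", "CCO",
            "O=C1CN=C(c2ccccc2)c2cc([N+](=O)[O-])ccc2N1C")
  for (smi in mols) {
    g <- parse_smiles(smi)
    total <- sum(atom_vsa(g))
    expect_equal(sum(slogp_vsa_bins(g)), total, tolerance = 1e-6)
    ac <- atom_contributions(g)
    hyd <- sum(ac$vsa[abs(ac$charge) <= 0.2])
    pol <- sum(ac$vsa[abs(ac$charge) > 0.2])
    expect_equal(hyd + pol, total, tolerance = 1e-9)
  }
})

test_that("hexane is entirely hydrophobic and apolar", {
  d <- compute_descriptors(HEXANE)
  g <- parse_smiles(HEXANE)
  expect_equal(d$h_log_pbo, 0)
  expect_equal(d$vsa_pol, 0)
  expect_equal(d$q_vsa_hyd, sum(atom_vsa(g)), tolerance = 1e-9)
})

test_that("unknown elements are rejected by name", {
  expect_error(parse_smiles("[SiH4]"), "Si")
})
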