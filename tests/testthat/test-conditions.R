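test_that("group copper converts to protein concentrations", {
  cup <- protein_from_copper(2.8, 8, 0.30)
  expect_equal(cup$holo, 0.35)
  expect_equal(cup$total, 0.35 / 0.30)
  expect_equal(cup$apo, cup$total - cup$holo)
  oth <- protein_from_copper(0.67, 1, 0.30)
  expect_equal(oth$holo, 0.67)
  expect_equal(signif(oth$total, 2), 2.2)
  expect_equal(signif(oth$apo, 2), 1.6)
  expect_error(protein_from_copper(-1, 8, 0.3), "nonnegative")
  expect_error(protein_from_copper(1, 0, 0.3), ">= 1")
  expect_error(protein_from_copper(1, 8, 0), "occupancy")
  expect_error(protein_from_copper(1, 8, 1.2), "occupancy")
})

test_that("transcription-factor partition respects the titration curve", {
  fit <- default_hill_fits()$MAC
  p <- mac_ace_partition(0.59, total = 1.5, fit)
  expect_equal(p$apo + p$holo, p$total)
  expect_equal(p$apo / p$total, hill_apo_fraction(0.59, fit))
  # more copper, less apo
  p2 <- mac_ace_partition(1.2, total = 1.5, fit)
  expect_lt(p2$apo, p$apo)
})

test_that("CTR tracks apo-MAC with the reference ratio", {
  expect_equal(ctr_from_amac(0.37), 0.79 * 0.37)
  expect_equal(signif(0.29 / 0.37, 2), 0.78) # measured ratio motivating 0.79
  expect_error(ctr_from_amac(-1), "nonnegative")
})

test_that("atoms-per-cell magnitudes match the published estimates", {
  # ~25,000 atoms of labile copper at 1 uM in a 42 fL cell
  expect_equal(atoms_per_cell(1e-6), 42e-15 * 6.02214076e23 * 1e-6)
  expect_lt(abs(atoms_per_cell(1e-6) / 25000 - 1), 0.05)
  # aqueous copper at 1e-18 M: about one atom per 40 million cells
  expect_lt(abs(atoms_per_cell(1e-18) * 40e6 - 1), 0.05)
  expect_error(atoms_per_cell(-1), "invalid")
})

test_that("condition input table is well formed", {
  raw <- cu_condition_fixture()
  expect_equal(raw$condition,
               c("MBCS", "M0", "M10", "M50", "M100", "M175", "M250"))
  expect_true(all(diff(raw$copper) > 0))
  expect_true(all(diff(raw$cu_cup) > 0))
  expect_true(all(diff(raw$cu_cu) > 0))
  expect_true(all(raw$occ_cup > 0 & raw$occ_cup < 1))
  expect_true(all(raw$occ_oth > 0 & raw$occ_oth < 1))
  m10 <- raw[raw$condition == "M10", ]
  expect_equal(m10$cu_cup, 2.8)
  expect_equal(m10$cu_oth, 0.67)
  expect_equal(m10$cu_cu, 0.59)
  expect_equal(m10$occ_cup, 0.30)
  expect_equal(m10$occ_oth, 0.30)
})

test_that("assembled condition table reproduces the reference condition", {
  m10 <- cf_conds[cf_conds$condition == "M10", ]
  expect_equal(m10$aMAC, 0.37)
  expect_equal(m10$CTR, 0.79 * 0.37)
  expect_equal(m10$CU, 0.59)
  expect_equal(m10$CUP, 0.35)
  expect_equal(m10$aCUP, 0.35 / 0.30 - 0.35)
  expect_equal(m10$OTH, 0.67)
  expect_equal(m10$aOTH, 0.67 / 0.30 - 0.67)
})

test_that("assembled table satisfies its anchors and invariances", {
  # Cu-deficient total cellular copper anchor
  expect_equal(cf_conds$total_cell_cu[cf_conds$condition == "MBCS"], 5.5)
  # invariant transcription-factor totals
  expect_equal(stats::sd(cf_conds$aMAC + cf_conds$MAC), 0)
  expect_equal(stats::sd(cf_conds$aACE + cf_conds$ACE), 0)
  # CTR proportional to apo-MAC everywhere
  expect_equal(cf_conds$CTR, 0.79 * cf_conds$aMAC)
  # total copper is the weighted component sum
  w <- cu_weight_vector(cf_net)
  expect_equal(cf_conds$total_cell_cu,
               as.numeric(as.matrix(cf_conds[names(w)]) %*% w))
  expect_true(all(as.matrix(cf_conds[cf_comp]) > 0))
  expect_true(all(diff(cf_conds$total_cell_cu) > 0))
})

test_that("assembly validates its inputs", {
  raw <- cu_condition_fixture()
  expect_error(assemble_condition_table(raw[raw$condition != "M10", ]),
               "M10")
  expect_error(assemble_condition_table(raw[raw$condition != "MBCS", ]),
               "MBCS")
  expect_error(assemble_condition_table(raw, mbcs_total_cu = 0.1),
               "nonpositive ACE")
})

test_that("reference state extraction matches the M10 row", {
  expect_equal(cf_ref$concentrations, cf_m10_state)
  expect_equal(cf_ref$alpha, 0.0033)
  expect_equal(cf_ref$copper_by_condition[["M10"]], 14)
  expect_error(reference_from_conditions(cf_conds, reference_condition = "M7"),
               "not found")
  expect_error(cu_reference(c(a = -1)), "positive")
})

test_that("condition tables round-trip through TSV", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_condition_table(cf_conds, tmp)
  back <- read_condition_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(cf_conds),
               tolerance = 1e-12)
})
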