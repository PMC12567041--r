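test_that("clearance partition reproduces the biliary-corrected UGT split", {
  pf <- partition_clearance(
    ugt_total = 0.583, bcrp_ft = 0.311,
    ugt_splits = c(UGT1A34 = 0.242, UGT2B7 = 0.479, UGT2B17 = 0.279),
    cyp_fms = c(CYP3A4 = 0.351, CYP2C8 = 0.005, CYP2D6 = 0.002,
                CYP2J2 = 0.0076),
    fe = 0.044, f_hyd = 0.0071)
  expect_equal(pf$ugt_revised, 0.272, tolerance = 1e-12)
  expect_equal(round(100 * pf$fm[["UGT2B7"]], 1), 13.0)
  expect_equal(round(pf$fm[["UGT2B17"]], 3), 0.076)
  expect_equal(round(pf$fm[["UGT1A34"]], 3), 0.066)
  expect_lt(abs(pf$total - 1), 0.01)
  # invariant to the ordering of the split vector
  pf2 <- partition_clearance(0.583, 0.311,
                             c(UGT2B17 = 0.279, UGT1A34 = 0.242, UGT2B7 = 0.479),
                             c(CYP3A4 = 0.351, CYP2C8 = 0.005, CYP2D6 = 0.002,
                               CYP2J2 = 0.0076), 0.044, 0.0071)
  expect_equal(pf2$fm[["UGT2B7"]], pf$fm[["UGT2B7"]])
  expect_error(partition_clearance(0.3, 0.4, c(a = 1), c(), 0, 0),
               "exceeds")
})

test_that("no-transporter limit apportions the full UGT total", {
  pf <- partition_clearance(0.583, 0, c(UGT2B7 = 0.5, UGT2B17 = 0.5),
                            c(CYP3A4 = 0.3659), fe = 0.044, f_hyd = 0.0071)
  expect_equal(pf$fm[["UGT2B7"]], 0.583 * 0.5)
})

test_that("biliary fraction from the with/without clearance pair", {
  expect_equal(round(bcrp_fraction(7.19, 4.96), 2), 0.31)
  expect_equal(bcrp_fraction(5, 5), 0)
  expect_equal(bcrp_fraction(10, 5), 0.5)
  # scale invariance
  expect_equal(bcrp_fraction(7.19, 4.96), bcrp_fraction(71.9, 49.6))
  expect_error(bcrp_fraction(4, 5), "clf_with")
})

test_that("renal clearance sits at ~56% of unbound filtration", {
  expect_equal(round(renal_fraction_check(1.8, 0.027, 120), 2), 0.56)
  expect_equal(renal_fraction_check(3.24, 0.027, 120), 1)
  expect_equal(ml_min_to_l_h(1.8), 0.108)
})

test_that("retrograde translation scales linearly and handles null pathways", {
  cmp <- load_compound("asciminib")
  ms <- mean_subject()
  fr <- ascipbpk:::asciminib_fractions(cmp)
  km <- setNames(vapply(cmp$enzymes, `[[`, 0, "km_u"),
                 vapply(cmp$enzymes, `[[`, "", "enzyme"))
  rg1 <- retrograde_vmax(fr, 7.19, km, ms, cmp)
  # the inversion is super-linear in the clearance target because of the
  # passive-diffusion barrier; it becomes exactly linear when the barrier
  # is effectively absent
  rg2 <- retrograde_vmax(fr, 2 * 7.19, km, ms, cmp)
  expect_true(all(rg2$vmax >= 2 * rg1$vmax - 1e-9))
  open_cmp <- unclass(cmp)
  open_cmp$transporters[[1]]$cl_pd <- 1e6
  open_cmp <- validate_compound(open_cmp)
  ra <- retrograde_vmax(fr, 7.19, km, ms, open_cmp)
  rb <- retrograde_vmax(fr, 2 * 7.19, km, ms, open_cmp)
  expect_equal(rb$vmax, 2 * ra$vmax, tolerance = 1e-6)
  # a pathway with fm 0 gets Vmax 0
  fr0 <- fr; fr0$fm[["CYP2C8"]] <- 0
  expect_equal(retrograde_vmax(fr0, 7.19, km, ms, cmp)$vmax[["CYP2C8"]], 0)
  # zero abundance with positive fm is an error
  ms0 <- ms; ms0$enzyme_abundance[["CYP2C8"]] <- 0
  expect_error(retrograde_vmax(fr, 7.19, km, ms0, cmp), "abundance")
  # back-calculated CYP3A4 Vmax lands near the reference output within the
  # abundance uncertainty (exact agreement is not expected)
  expect_gt(rg1$vmax[["CYP3A4"]], 3.8 / 2.5)
  expect_lt(rg1$vmax[["CYP3A4"]], 3.8 * 2.5)
  expect_equal(rg1$fg, 0.83, tolerance = 1e-9)
  expect_equal(rg1$fh, 0.92, tolerance = 0.02)
})
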