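test_that("the asciminib fixture carries the reference parameterization", {
  cmp <- load_compound("asciminib")
  expect_s3_class(cmp, "pbpk_compound")
  expect_equal(cmp$binding$fu_plasma, 0.027)
  expect_equal(cmp$absorption$ka, 1.3)
  expect_equal(cmp$distribution$kp_scalar, 0.025)
  expect_equal(cmp$physchem$molecular_weight, 449.85)
  expect_equal(cmp$binding$blood_to_plasma, 0.80)
  expect_equal(cmp$absorption$fu_gut, 0.25)
  expect_equal(cmp$absorption$q_gut, 5.3)
  enz <- setNames(cmp$enzymes, vapply(cmp$enzymes, `[[`, "", "enzyme"))
  expect_equal(enz$CYP3A4$vmax, 3.8)
  expect_equal(enz$CYP3A4$km_u, 15.7)
  expect_equal(enz$UGT2B7$fm_target, 0.131)
  tr <- cmp$transporters[[1]]
  expect_equal(tr$jmax, 0.2782)
  expect_equal(tr$km, 0.0070865)
  expect_equal(tr$cl_pd, 0.06)
  expect_equal(cmp$renal$cl_renal, 0.108)
})

test_that("pathway fm/ft/fe targets of the fixture sum to one", {
  cmp <- load_compound("asciminib")
  tot <- sum(vapply(cmp$enzymes, `[[`, 0, "fm_target")) +
    cmp$transporters[[1]]$ft_target_low_dose +
    cmp$renal$fe_target + cmp$additional_clearance$fm_target
  expect_lt(abs(tot - 1), 0.01)
})

test_that("validation errors name the offending field", {
  cmp <- unclass(load_compound("asciminib"))
  cmp$physchem$molecular_weight <- NULL
  expect_error(validate_compound(cmp), "molecular_weight")
  cmp2 <- unclass(load_compound("asciminib"))
  cmp2$absorption$ka <- -1
  expect_error(validate_compound(cmp2), "ka")
  cmp3 <- unclass(load_compound("midazolam"))
  cmp3$binding$fu_plasma <- 0
  expect_error(validate_compound(cmp3), "fu_plasma")
})

test_that("serialization round trips losslessly for every fixture", {
  for (nm in compound_fixtures()) {
    cmp <- load_compound(nm)
    f <- tempfile(fileext = ".yaml")
    write_compound(cmp, f)
    back <- load_compound(f)
    expect_equal(back, cmp, info = nm)
    unlink(f)
  }
})

test_that("IC50-to-Ki conversions follow the three conventions", {
  expect_equal(ki_from_ic50(20.8, "half"), 10.4)
  expect_equal(round(ki_from_ic50(0.56, "substrate-corrected",
                                  S = 10, km_probe = 16.8), 2), 0.35)
  expect_equal(ki_from_ic50(5, "direct"), 5)
  # S = 0 reduces substrate-corrected mode to the direct conversion
  expect_equal(ki_from_ic50(3.7, "substrate-corrected", S = 0, km_probe = 10),
               3.7)
  expect_error(ki_from_ic50(-1, "half"), "ic50_u")
})

test_that("ki_from_ic50 is monotone in IC50 and in substrate concentration", {
  ic <- seq(0.1, 50, length.out = 25)
  k <- ki_from_ic50(ic, "substrate-corrected", S = 5, km_probe = 12)
  expect_true(all(diff(k) > 0))
  S <- seq(0, 40, length.out = 25)
  k2 <- vapply(S, function(s) {
    ki_from_ic50(10, "substrate-corrected", S = s, km_probe = 12)
  }, 0)
  expect_true(all(diff(k2) < 0))
})

test_that("unbound Km correction multiplies by fu_mic and inverts", {
  expect_equal(km_unbound(42, 1), 42)
  # the reference CYP3A4 pair: Km_u 15.7 with fu_mic 0.160
  km_app <- 15.7 / 0.160
  expect_equal(km_unbound(km_app, 0.160), 15.7, tolerance = 1e-12)
  expect_equal(round(km_app, 1), 98.1)
  expect_error(km_unbound(10, 0), "fu_mic")
})
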