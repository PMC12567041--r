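probe_mdz <- list(pathways = c(CYP3A4 = 0.94), fg = 0.57,
                  gut_enzyme = "CYP3A4")

test_that("net-effect ratio is unity for a null perpetrator", {
  inp <- list(imax_u_inlet = 0, igut_u = 0, ki_u = list(CYP3A4 = 1))
  expect_equal(net_effect_aucr(inp, probe_mdz), 1)
  # induction-only perpetrator with Indmax = 1 (Emax 0) is also null
  inp2 <- list(imax_u_inlet = 5, igut_u = 5, ki_u = list(),
               induction = list(CYP3A4 = list(indc50 = 1, emax = 0)))
  expect_equal(net_effect_aucr(inp2, probe_mdz), 1)
})

test_that("net-effect reduces to 1 + I/Ki for a pure hepatic probe", {
  probe <- list(pathways = c(CYP3A4 = 1), fg = 1, gut_enzyme = "none")
  inp <- list(imax_u_inlet = 0.7, igut_u = 0, ki_u = list(CYP3A4 = 0.35))
  expect_equal(net_effect_aucr(inp, probe), 1 + 0.7 / 0.35)
})

test_that("R3 has its plateau and null limits", {
  expect_equal(r3(2, 0.5, 1), 1)
  expect_equal(r3(1e9, 0.5, 5), 1 / 5, tolerance = 1e-6)
  expect_equal(r3(0.5, 0.5, 3, d = 1), 1 / (1 + 2 * 0.5), tolerance = 1e-12)
})

test_that("RIS is zero at zero exposure and monotone increasing", {
  expect_equal(ris(4.4, 2.7, 0), 0)
  v <- vapply(seq(0, 2, length.out = 20), function(i) ris(4.4, 2.7, i), 0)
  expect_true(all(diff(v) > 0))
})

test_that("R3 and RIS order perpetrator exposures consistently", {
  ii <- seq(0.01, 3, length.out = 15)
  r3v <- vapply(ii, function(i) r3(i, 0.59, 4.5), 0)
  risv <- vapply(ii, function(i) ris(3.5, 0.59, i), 0)
  expect_equal(order(r3v), rev(order(risv)))
})

test_that("induction calibration matches the printed pair and is idempotent", {
  cal <- calibrate_induction(list(indc50 = 2.7, indmax = 5.4))
  expect_equal(cal$indc50, 2.057, tolerance = 1e-3)
  expect_equal(cal$indmax, 1.53, tolerance = 1e-3)
  # identity when the reference in vivo equals the reference in vitro
  ref <- list(indc50 = 0.42, emax = 124)
  same <- calibrate_induction(list(indc50 = 2.7, indmax = 5.4), ref, ref)
  expect_equal(same$indc50, 2.7)
  expect_equal(same$indmax, 5.4)
  # doubling the test Emax doubles the calibrated Emax
  cal2 <- calibrate_induction(list(indc50 = 2.7, indmax = 1 + 2 * 4.4))
  expect_equal(cal2$emax, 2 * cal$emax, tolerance = 1e-12)
  expect_error(calibrate_induction(list(indc50 = 2.7, indmax = 5.4),
                                   list(indc50 = 0, emax = 1),
                                   list(indc50 = 1, emax = 1)), "positive")
})
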