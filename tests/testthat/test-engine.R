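test_that("zero dose gives an all-zero trajectory", {
  sys <- build_system(asc_model(), list(), ref_subject())
  prof <- simulate_profile(sys, NULL, list(), duration = 24)
  expect_true(all(abs(attr(prof, "state")[, -1][, 1:30]) < 1e-12))
})

test_that("mass is conserved to well under 0.1% of dose", {
  sys <- build_system(asc_model(), list(), ref_subject())
  prof <- simulate_profile(sys, regimen(40, "BID", n_days = 3), duration = 96)
  expect_lt(abs(mass_balance_error(prof)), 1e-3)
})

test_that("unknown engine options and bad perpetrators are rejected", {
  expect_error(build_system(asc_model(), list(), ref_subject(),
                            options = list(bcrpp = TRUE)), "unknown option")
  expect_error(build_system(asc_model(), list(load_compound("asciminib")),
                            ref_subject()), "reduced")
})

test_that("BCRP efflux saturates to its maximal rate at high exposure", {
  sys <- build_system(asc_model(), list(), ref_subject())
  jmax <- sys$vic[27]
  # steady state at the highest dose: instantaneous biliary flux close to Jmax
  prof <- simulate_profile(sys, regimen(200, "BID", n_days = 10),
                           duration = 242)
  st <- attr(prof, "state")
  i <- which(st[, 1] >= 236 & st[, 1] <= 240)
  bile_rate <- diff(st[range(i), 19]) / diff(st[range(i), 1])
  expect_gt(bile_rate / jmax, 0.85)
  expect_lt(bile_rate / jmax, 1.0)
})

test_that("with BCRP disabled and linearized kinetics AUC is dose-proportional", {
  opts <- list(bcrp = FALSE, linearize_mm = TRUE)
  sys <- build_system(asc_model(), list(), ref_subject(), opts)
  a <- vapply(c(20, 80), function(d) {
    pk_metrics(simulate_profile(sys, regimen(d, "single"), duration = 96),
               "asciminib", 0, Inf)$auc_inf
  }, 0)
  expect_equal(a[2] / a[1], 4, tolerance = 1e-4)
})

test_that("a co-simulated perpetrator with interactions off leaves the victim bit-identical", {
  solo <- build_system(asc_model(), list(), ref_subject())
  both <- build_system(asc_model(), list("clarithromycin"), ref_subject(),
                       options = list(interactions = FALSE))
  rg <- regimen(40, "single")
  p1 <- simulate_profile(solo, rg, duration = 48)
  p2 <- simulate_profile(both, rg, list(regimen(500, "BID", 2)), duration = 48)
  expect_identical(p1$asciminib, p2$asciminib)
})

test_that("first-pass components multiply to the oral bioavailability", {
  fp <- first_pass(asc_model())
  expect_true(fp$fg >= 0.82 && fp$fg <= 0.84)
  expect_equal(fp$fh, 0.92, tolerance = 0.02)
  expect_equal(fp$f, 0.73, tolerance = 0.015)
  expect_equal(fp$f, fp$fa * fp$fg * fp$fh, tolerance = 1e-12)
  # shutting down gut metabolism pushes Fg to 1; doubling it lowers Fg
  expect_equal(first_pass(asc_model(), gut_clint_fold = 0)$fg, 1)
  expect_lt(first_pass(asc_model(), gut_clint_fold = 2)$fg, fp$fg)
})

test_that("inhibition modifier has the competitive closed form", {
  expect_equal(inhibition_modifier(10, 0, 1), 10)
  expect_equal(inhibition_modifier(10, 1, 1), 5)
  expect_equal(inhibition_modifier(12, c(1, 2), c(2, 4)), 6)
})

test_that("induction turnover reaches the closed-form steady state and washes out", {
  kdeg <- 0.03
  expect_equal(induction_dynamics(1, 0, 0.5, 4, kdeg), 0)
  ss <- induction_steady_state(2, 0.5, 4)
  expect_equal(induction_dynamics(ss, 2, 0.5, 4, kdeg), 0, tolerance = 1e-12)
  # washout from an induced state decays at kdeg
  expect_equal(induction_dynamics(2, 0, 0.5, 4, kdeg), -kdeg * 1)
})

test_that("enterohepatic recirculation off is the identity and AUC is monotone", {
  base <- build_system(asc_model(), list(), ref_subject())
  rg <- regimen(40, "single")
  p0 <- simulate_profile(base, rg, duration = 96)
  pOff <- simulate_profile(ehc_toggle(base, 0), rg, duration = 96)
  expect_identical(p0$asciminib, pOff$asciminib)
  aucs <- vapply(c(0, 0.4, 1), function(f) {
    pk_metrics(simulate_profile(ehc_toggle(base, f), rg, duration = 96),
               "asciminib", 0, Inf)$auc_inf
  }, 0)
  expect_true(all(diff(aucs) > 0))
  expect_error(ehc_toggle(base, 1.4), "reabsorbed_fraction")
})
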