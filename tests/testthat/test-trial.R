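test_that("regimen schedules expand correctly", {
  expect_equal(ascipbpk:::regimen_times(regimen(40, "BID", n_days = 2)),
               c(0, 12, 24, 36))
  expect_equal(ascipbpk:::regimen_times(regimen(4, "single", start_day = 3)), 48)
  expect_equal(ascipbpk:::regimen_times(
    regimen(400, "single", start_day = 3, offset_h = 1)), 49)
  expect_equal(ascipbpk:::regimen_times(regimen(100, "TID", n_days = 1)),
               c(0, 8, 16))
  expect_error(regimen(-1, "QD"), "dose")
})

test_that("geometric mean ratios follow the closed forms", {
  r <- ddi_ratio(c(2, 8), c(1, 1), paired = TRUE)
  expect_equal(r$gmr, 4)
  same <- ddi_ratio(c(1.2, 0.9, 1.4), c(1.2, 0.9, 1.4), paired = TRUE)
  expect_equal(same$gmr, 1)
  expect_true(same$ci[1] <= 1 && same$ci[2] >= 1)
  # invariance to concentration units (both arms rescaled)
  x <- c(100, 140, 90); y <- c(80, 100, 85)
  expect_equal(ddi_ratio(x, y)$gmr, ddi_ratio(x * 1e3, y * 1e3)$gmr)
  expect_warning(ddi_ratio(c(1, 0), c(1, 1)), "excluded")
})

test_that("a trial is reproducible under its seed", {
  d <- trial_design(list(asciminib = regimen(40, "single")),
                    analyte = "asciminib", n_trials = 2, n_subjects = 2,
                    seed = 42)
  t1 <- run_trial(d, washout_h = 48)
  t2 <- run_trial(d, washout_h = 48)
  expect_identical(t1$metrics, t2$metrics)
  s <- trial_summary(t1, "treated")
  expect_equal(s$n, 4)
  expect_true(s$cmax_cv > 0)
})

test_that("a non-interacting perpetrator arm gives a ratio of exactly 1 per subject", {
  d <- trial_design(list(asciminib = regimen(40, "single"),
                         clarithromycin = regimen(500, "BID", n_days = 2)),
                    analyte = "asciminib", n_trials = 1, n_subjects = 3,
                    seed = 8)
  tr <- run_trial(d, perpetrators = list("clarithromycin"),
                  options = list(interactions = FALSE), washout_h = 48)
  a <- tr$metrics
  ratio <- a$auc_inf[a$arm == "treated"] / a$auc_inf[a$arm == "control"]
  expect_identical(ratio, rep(1, 3))
})

test_that("healthy-versus-healthy organ-impairment contrast is unity", {
  r <- oi_study("none", 40, n_trials = 1, n_subjects = 3, seed = 4)
  expect_equal(r$auc$gmr, 1, tolerance = 1e-9)
  expect_equal(r$cmax$gmr, 1, tolerance = 1e-9)
})
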