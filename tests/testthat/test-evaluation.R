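test_that("percent prediction error matches the printed spot values", {
  expect_equal(round(percent_pe(625, 567), 1), 10.2)
  expect_equal(round(percent_pe(5490, 6040), 2), -9.11)
  expect_equal(percent_pe(100, 100), 0)
  expect_error(percent_pe(1, 0), "observed")
})

test_that("fold errors have their closed-form special cases", {
  one <- afe_aafe(1.5, 1)
  expect_equal(unname(one["afe"]), 1.5)
  expect_equal(unname(one["aafe"]), 1.5)
  sym <- afe_aafe(c(2, 0.5), c(1, 1))
  expect_equal(unname(sym["afe"]), 1)
  expect_equal(unname(sym["aafe"]), 2)
  expect_equal(gmfe(c(1.2, 0.9), c(1.2, 0.9)), 1)
  expect_warning(afe_aafe(c(1, -2), c(1, 1)), "excluded")
})

test_that("fold-error invariants hold on random pairs", {
  set.seed(31)
  for (i in 1:20) {
    p <- rlnorm(8); o <- rlnorm(8)
    s <- afe_aafe(p, o)
    expect_gte(s[["aafe"]], 1)
    expect_gte(s[["aafe"]], max(s[["afe"]], 1 / s[["afe"]]))
    inv <- afe_aafe(o, p)
    expect_equal(inv[["afe"]], 1 / s[["afe"]], tolerance = 1e-12)
  }
})

test_that("Guest limits give the classical bounds at unity with 20% variability and are reciprocal", {
  expect_equal(unname(guest_limits(1, 20)), c(0.8, 1.25))
  expect_equal(unname(guest_limits(1, 0)), c(1, 1))
  for (r in c(0.4, 0.851, 1.28, 2.2)) {
    a <- guest_limits(r)
    b <- guest_limits(1 / r)
    expect_equal(unname(sort(1 / b)), unname(sort(a)), tolerance = 1e-12)
  }
  expect_true(guest_flag(1.23, 1.28))              # midazolam
  expect_false(guest_flag(0.566, 0.851))           # rifampicin, no variability
  expect_false(guest_flag(1.24, 1.04))             # itraconazole AUC
  expect_true(guest_flag(1.24, 1.04, intra_subject_cv = 20))
})

test_that("twofold and 25% bounds use the log10 cutoffs", {
  b <- bounds_checks(c(1, 1.19, 0.602, 2.2), rep(1, 4))
  expect_equal(b$within_twofold, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(b$within_25pct, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("the transcribed PK table reproduces every printed summary statistic", {
  t2 <- table2_pk_reference()
  expect_equal(nrow(t2), 31)
  cm <- afe_aafe(t2$cmax_sim, t2$cmax_obs)
  expect_equal(round(cm[["afe"]], 2), 1.00)
  expect_equal(round(cm[["aafe"]], 2), 1.10)
  au <- afe_aafe(t2$auc_sim, t2$auc_obs)
  expect_equal(round(au[["afe"]], 2), 1.14)
  expect_equal(round(au[["aafe"]], 2), 1.17)
  ok <- !is.na(t2$ctrough_obs)
  ct <- afe_aafe(t2$ctrough_sim[ok], t2$ctrough_obs[ok])
  expect_equal(round(ct[["afe"]], 2), 1.13)
  expect_equal(round(ct[["aafe"]], 2), 1.29)
  # recomputed per-row prediction errors agree with the printed ones in
  # magnitude (one printed Cmax %PE carries a sign inconsistent with its
  # own observed/simulated pair)
  pe <- percent_pe(t2$cmax_sim, t2$cmax_obs)
  expect_lt(max(abs(abs(pe) - abs(t2$pe_cmax_printed))), 0.15)
  pe2 <- percent_pe(t2$auc_sim, t2$auc_obs)
  expect_lt(max(abs(pe2 - t2$pe_auc_printed)), 0.15)
})

test_that("the transcribed ratio table reproduces the printed GMFE row", {
  t3 <- table3_ratio_reference()
  expect_equal(nrow(t3), 11)
  expect_equal(round(gmfe(t3$cmax_sim, t3$cmax_obs), 2), 1.18)
  expect_equal(round(gmfe(t3$auc_sim, t3$auc_obs), 2), 1.14)
  rpo <- t3$auc_sim / t3$auc_obs
  expect_lt(max(abs(rpo - t3$auc_rpo_printed)), 0.006)
  rpc <- t3$cmax_sim / t3$cmax_obs
  expect_lt(max(abs(rpc - t3$cmax_rpo_printed)), 0.006)
})

test_that("evaluation report assembles pairs and summary", {
  r <- evaluation_report(c(2, 1), c(1, 1), label = c("a", "b"), metric = "auc")
  expect_equal(nrow(r$pairs), 2)
  expect_equal(r$summary$afe[[1]], sqrt(2), tolerance = 1e-12)
  expect_output(print(r), "evaluation_report")
})
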