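test_that("sampling is reproducible under a seed and independent across seeds", {
  spec <- population_spec()
  a <- sample_population(spec, 5, seed = 11)
  b <- sample_population(spec, 5, seed = 11)
  expect_identical(a, b)
  c3 <- sample_population(spec, 5, seed = 12)
  expect_false(identical(a, c3))
  # sampling does not disturb the caller's random stream
  set.seed(99); x1 <- rnorm(1)
  set.seed(99); invisible(sample_population(spec, 3, seed = 5)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("demographics follow the population spec", {
  spec <- population_spec(age_range = c(25, 40), female_proportion = 1)
  pop <- sample_population(spec, 20, seed = 3)
  ages <- vapply(pop, `[[`, 0, "age")
  expect_true(all(ages >= 25 & ages <= 40))
  expect_true(all(vapply(pop, `[[`, "", "sex") == "female"))
  expect_error(population_spec(impairment = "CP-Z"), "unknown impairment")
  expect_error(population_spec(base = "piglet"), "unknown population base")
})

test_that("renal-impairment subjects fall inside the declared GFR bin", {
  for (lab in c("RI-mild", "RI-moderate", "RI-severe")) {
    pop <- sample_population(population_spec(impairment = lab), 25, seed = 7)
    g <- vapply(pop, `[[`, 0, "gfr")
    bin <- physiology_constants()$ri_bins[[lab]]
    expect_true(all(g >= bin$gfr_low & g < bin$gfr_high), info = lab)
  }
})

test_that("the UGT-modified CP-C population reduces UGT1A4 and UGT2B7 by 85%", {
  pop <- sample_population(population_spec(impairment = "CP-C-ugt-modified"),
                           300, seed = 5)
  ab <- t(vapply(pop, function(s) s$enzyme_abundance[c("UGT1A4", "UGT2B7")],
                 c(UGT1A4 = 0, UGT2B7 = 0)))
  expect_equal(mean(ab[, "UGT1A4"]), 7.8, tolerance = 0.08)
  expect_equal(mean(ab[, "UGT2B7"]), 10.65, tolerance = 0.08)
  # CP classes leave the remaining UGTs untouched
  s0 <- mean_subject()
  s1 <- apply_impairment(s0, "CP-B")
  expect_equal(s1$enzyme_abundance[["UGT1A3"]], s0$enzyme_abundance[["UGT1A3"]])
  expect_lt(s1$enzyme_abundance[["CYP3A4"]], s0$enzyme_abundance[["CYP3A4"]])
})

test_that("impairment 'none' is the identity", {
  s <- mean_subject()
  expect_identical(apply_impairment(s, "none"), s)
})

test_that("population means converge to the declared central values", {
  pop <- sample_population(population_spec(female_proportion = 0), 400, seed = 2)
  pc <- physiology_constants()
  bw <- vapply(pop, `[[`, 0, "body_weight")
  expect_equal(mean(bw), pc$sex$male$body_weight_kg, tolerance = 0.05)
  ab3a4 <- vapply(pop, function(s) s$enzyme_abundance[["CYP3A4"]], 0)
  expect_equal(mean(ab3a4), pc$enzyme_abundance$CYP3A4$mean, tolerance = 0.08)
  gfr <- vapply(pop, `[[`, 0, "gfr")
  expect_equal(mean(gfr), pc$variability$gfr_healthy_mean, tolerance = 0.05)
})

test_that("healthy and cancer bases give closely similar asciminib PK", {
  m <- asc_model()
  pk <- function(base) {
    s <- mean_subject(base = base)
    prof <- simulate_profile(build_system(m, list(), s), regimen(40, "single"),
                             duration = 96)
    pk_metrics(prof, "asciminib", 0, Inf)
  }
  h <- pk("healthy"); k <- pk("cancer")
  expect_lt(abs(k$auc_inf / h$auc_inf - 1), 0.15)
  expect_lt(abs(k$cmax / h$cmax - 1), 0.15)
})
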