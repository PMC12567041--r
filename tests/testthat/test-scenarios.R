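small_cfg <- function() {
  list(scenario_id = "tiny_pk", type = "pk_summary", analyte = "asciminib",
       regimens = list(asciminib = list(dose = 40, interval = "single")),
       population = list(base = "healthy"),
       n_trials = 1, n_subjects = 2, seed = 9)
}

test_that("the same scenario config reproduces identical outputs", {
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_scenario(small_cfg(), d1)
  r2 <- run_scenario(small_cfg(), d2)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
  f1 <- file.path(d1, "tiny_pk_summary.tsv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(file.path(d2, "tiny_pk_summary.tsv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a scenario with an unknown compound fails before simulation", {
  cfg <- small_cfg()
  cfg$regimens$nosuchdrug <- list(dose = 1, interval = "QD")
  expect_error(run_scenario(cfg), "unknown compound")
})

test_that("an empty suite yields an empty report and no errors", {
  s <- run_suite(list())
  expect_equal(nrow(s$ratios), 0)
  expect_length(s$errors, 0)
})

test_that("suite execution isolates individual failures", {
  bad <- small_cfg(); bad$scenario_id <- "bad"; bad$type <- "nope"
  s <- run_suite(list(bad, small_cfg()))
  expect_length(s$errors, 1)
  expect_named(s$results, "tiny_pk")
})

test_that("shipped scenario configs are discoverable and well formed", {
  fs <- scenario_fixtures()
  expect_true(length(fs) >= 4)
  ids <- vapply(fs, function(f) yaml::read_yaml(f)$scenario_id, "")
  expect_false(any(duplicated(ids)))
})
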