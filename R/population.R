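#' Define a virtual population
#'
#' A population specification combines a base physiology (healthy or
#' cancer), an optional organ-impairment label, the demographic window and
#' the between-subject variability model (log-normal CVs carried in the
#' physiology file).
#'
#' @param base `"healthy"` or `"cancer"`.
#' @param impairment one of `"none"`, `"CP-A"`, `"CP-B"`, `"CP-C"`,
#'   `"CP-C-ugt-modified"`, `"RI-mild"`, `"RI-moderate"`, `"RI-severe"`.
#' @param age_range adult age window in years (length-2 numeric).
#' @param female_proportion proportion of female subjects in `[0, 1]`.
#' @return a `population_spec` object.
#' @export
population_spec <- function(base = "healthy", impairment = "none",
                            age_range = c(20, 55), female_proportion = 0.5) {
  pc <- physiology_constants()
  check_that(base %in% names(pc$bases), paste0("unknown population base: ", base))
  ok <- c("none", names(pc$impairment), names(pc$ri_bins))
  check_that(impairment %in% ok, paste0("unknown impairment label: ", impairment))
  check_that(length(age_range) == 2 && age_range[1] >= 18 && age_range[2] <= 85,
             "age_range must lie within adult bounds (18-85 years)")
  check_that(female_proportion >= 0 && female_proportion <= 1,
             "female_proportion must be in [0, 1]")
  structure(list(base = base, impairment = impairment,
                 age_range = as.numeric(age_range),
                 female_proportion = female_proportion),
            class = "population_spec")
}

#' Sample virtual subjects
#'
#' Draws `n` virtual individuals: demographics uniform over the spec's age
#' window, sex by the female proportion, and physiological quantities
#' (body weight, cardiac output, liver mass, microsomal protein,
#' hepatocellularity, enzyme and transporter abundances, passive-diffusion
#' scalar, GFR) from log-normal distributions around the reference values.
#' Impairment modifiers are applied to each sampled healthy subject via
#' [apply_impairment()], so an impaired cohort and its demographically
#' matched healthy control cohort can share a seed.
#'
#' @param spec a [population_spec()].
#' @param n number of subjects (> 0).
#' @param seed integer seed; the same seed reproduces the same subjects.
#' @return list of `pbpk_subject` objects.
#' @export
sample_population <- function(spec, n, seed) {
  check_that(inherits(spec, "population_spec"), "spec must be a population_spec")
  check_that(n > 0, "n must be positive")
  pc <- physiology_constants()
  v <- pc$variability
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      sex <- if (runif(1) < spec$female_proportion) "female" else "male"
      age <- runif(1, spec$age_range[1], spec$age_range[2])
      bw <- rlnorm_cv(1, pc$sex[[sex]]$body_weight_kg, v$body_weight_cv)
      draws <- list(
        co = rlnorm_cv(1, 1, 12),
        liver_mass = rlnorm_cv(1, 1, v$liver_mass_cv),
        mppgl = rlnorm_cv(1, 1, v$mppgl_cv),
        hpgl = rlnorm_cv(1, 1, v$hpgl_cv),
        clpd = rlnorm_cv(1, 1, v$clpd_cv),
        bcrp = rlnorm_cv(1, 1, pc$transporter_activity$BCRP$cv),
        gfr = max(20, rnorm(1, v$gfr_healthy_mean,
                            v$gfr_healthy_mean * v$gfr_healthy_cv / 100))
      )
      for (e in names(pc$enzyme_abundance)) {
        draws[[paste0("ab_", e)]] <- rlnorm_cv(1, 1, pc$enzyme_abundance[[e]]$cv)
      }
      s <- build_subject(pc, sex = sex, base = spec$base, age = age,
                         bw = bw, draws = draws)
      apply_impairment(s, spec$impairment)
    })
  })
}

#' Apply an organ-impairment modifier set to a healthy subject
#'
#' Child-Pugh classes scale functional liver mass, hepatic enzyme
#' abundance, hepatic/portal blood flow, plasma-protein binding, GFR,
#' hepatocellularity and canalicular transporter activity; the
#' UGT-modified CP-C variant additionally reduces UGT1A4 and UGT2B7
#' abundance by 85%. Renal-impairment labels draw the subject's GFR inside
#' the declared bin (deterministically positioned by the subject's own
#' healthy GFR percentile, so matched cohorts stay matched).
#'
#' @param subject a `pbpk_subject` sampled from a healthy base.
#' @param impairment impairment label (see [population_spec()]).
#' @return the modified `pbpk_subject`.
#' @export
apply_impairment <- function(subject, impairment) {
  if (impairment == "none") return(subject)
  pc <- physiology_constants()
  if (impairment %in% names(pc$ri_bins)) {
    bin <- pc$ri_bins[[impairment]]
    # map the subject's healthy GFR percentile into the bin
    v <- pc$variability
    p <- stats::pnorm(subject$gfr, v$gfr_healthy_mean,
                      v$gfr_healthy_mean * v$gfr_healthy_cv / 100)
    subject$gfr <- bin$gfr_low + p * (bin$gfr_high - bin$gfr_low) * 0.999
    subject$impairment <- impairment
    return(subject)
  }
  m <- pc$impairment[[impairment]]
  check_that(!is.null(m), paste0("unknown impairment label: ", impairment))
  subject$liver_mass <- subject$liver_mass * m$liver_mass
  ab <- subject$enzyme_abundance
  cyps <- grepl("^CYP", names(ab))
  ab[cyps] <- ab[cyps] * m$cyp_abundance
  ab[c("UGT1A4", "UGT2B7")] <- ab[c("UGT1A4", "UGT2B7")] * m$ugt_reduction
  subject$enzyme_abundance <- ab
  subject$tissue_blood_flows[c("gut", "spleen")] <-
    subject$tissue_blood_flows[c("gut", "spleen")] * m$q_hepatic
  subject$q_hepatic_arterial <- subject$q_hepatic_arterial * m$q_hepatic
  subject$fu_scalar <- subject$fu_scalar * m$fu_scalar
  subject$plasma_protein_scalar <- 1 / subject$fu_scalar
  subject$gfr <- subject$gfr * m$gfr
  subject$hepatocellularity <- subject$hepatocellularity * m$hepatocellularity
  subject$transporter_activity_scalar <-
    subject$transporter_activity_scalar * m$transporter
  subject$impairment <- impairment
  subject
}
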