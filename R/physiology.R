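#' Reference physiology constants
#'
#' Loads (and caches) the versioned physiology data file shipped with the
#' package: organ volumes and blood flows for a reference adult, hepatic
#' enzyme and transporter abundances with their between-subject
#' variability, impairment modifier sets (Child-Pugh classes, renal GFR
#' bins) and enzyme turnover constants.
#'
#' @return a nested list mirroring `inst/extdata/physiology.yaml`.
#' @export
physiology_constants <- function() {
  if (is.null(.ascipbpk_cache$phys_const)) {
    .ascipbpk_cache$phys_const <- yaml::read_yaml(extdata_path("physiology.yaml"))
  }
  .ascipbpk_cache$phys_const
}

# canonical tissue order used throughout the engine
TISSUES <- c("lung", "adipose", "bone", "brain", "gut", "heart", "kidney",
             "muscle", "skin", "spleen", "rest")

ENZYMES <- c("CYP3A4", "CYP2C8", "CYP2D6", "CYP2J2",
             "UGT1A3", "UGT1A4", "UGT2B7", "UGT2B17")

# enzyme id codes shared with the compiled right-hand side
ENZYME_IDS <- c(CYP3A4 = 1, CYP2C8 = 2, CYP2D6 = 3, CYP2J2 = 4,
                UGT1A3 = 5, UGT1A4 = 6, UGT2B7 = 7, UGT2B17 = 8,
                HYD = 9, BCRP = 10, CYP2C9 = 11, CYP2C19 = 12,
                CYP1A2 = 13, UGT1A1 = 14, OATP1B1 = 15)

#' Construct the mean (reference) virtual subject
#'
#' Builds a deterministic subject at the central values of the physiology
#' file: the "mean healthy subject" used for model calibration and for the
#' retrograde clearance translation.
#'
#' @param sex `"male"` or `"female"`; the default mean subject is male.
#' @param base population base, `"healthy"` or `"cancer"`.
#' @return a `pbpk_subject` list (see [sample_population()]).
#' @export
mean_subject <- function(sex = "male", base = "healthy") {
  pc <- physiology_constants()
  build_subject(pc, sex = sex, base = base,
                age = 35,
                bw = pc$sex[[sex]]$body_weight_kg,
                draws = NULL)
}

# shared constructor: draws = NULL gives central values, otherwise a list of
# multiplicative deviates sampled in sample_population()
build_subject <- function(pc, sex, base, age, bw, draws = NULL) {
  ref <- pc$reference
  d <- function(nm, default = 1) if (is.null(draws)) default else draws[[nm]]
  sx <- pc$sex[[sex]]
  size <- bw / ref$body_weight_kg

  vols <- vapply(TISSUES, function(t) pc$tissues[[t]]$volume_l, 0) * size
  vols[["adipose"]] <- vols[["adipose"]] * sx$adipose_scale
  vols[["muscle"]] <- vols[["muscle"]] * sx$muscle_scale

  co_b <- ref$cardiac_output_blood_l_h * size^0.75 * sx$co_scale * d("co")
  co_p <- co_b * (1 - ref$hematocrit)
  flows <- vapply(TISSUES, function(t) pc$tissues[[t]]$flow_frac, 0) * co_p
  flows[["lung"]] <- co_p
  q_ha <- pc$hepatic_arterial_flow_frac * co_p

  liver_mass <- ref$liver_mass_g * size^0.78 * d("liver_mass")
  ab <- vapply(names(pc$enzyme_abundance), function(e) {
    pc$enzyme_abundance[[e]]$mean * d(paste0("ab_", e))
  }, 0)
  bs <- pc$bases[[base]]
  cyps <- grepl("^CYP", names(ab))
  ab[cyps] <- ab[cyps] * bs$cyp_scalar
  ab[!cyps] <- ab[!cyps] * bs$ugt_scalar

  gfr <- if (is.null(draws)) pc$variability$gfr_healthy_mean else draws$gfr

  subject <- list(
    age = age, sex = sex, base = base, body_weight = bw,
    impairment = "none",
    tissue_volumes = vols,
    tissue_blood_flows = flows,      # plasma flows, L/h
    cardiac_output = co_p,           # plasma, L/h
    q_hepatic_arterial = q_ha,
    arterial_plasma = ref$arterial_plasma_l * size,
    venous_plasma = ref$venous_plasma_l * size,
    liver_extracellular = ref$liver_extracellular_l * size,
    liver_cell = ref$liver_cell_l * size,
    liver_mass = liver_mass,
    mppgl = ref$mppgl_mg_g * d("mppgl"),
    hepatocellularity = ref$hpgl_million_g * d("hpgl"),
    enzyme_abundance = ab,           # pmol/mg microsomal protein
    transporter_activity_scalar = c(BCRP = unname(pc$transporter_activity$BCRP$mean * d("bcrp"))),
    clpd_scalar = d("clpd"),
    gfr = gfr,                       # mL/min/1.73 m^2
    plasma_protein_scalar = 1 / bs$fu_scalar,
    fu_scalar = bs$fu_scalar,        # multiplies compound fu_plasma
    hematocrit = ref$hematocrit
  )
  class(subject) <- "pbpk_subject"
  subject
}

#' @export
print.pbpk_subject <- function(x, ...) {
  cat(sprintf("<pbpk_subject> %s, %s, %.0f kg, %s/%s, GFR %.0f mL/min\n",
              x$sex, paste0(x$age, " y"), x$body_weight, x$base,
              x$impairment, x$gfr))
  invisible(x)
}
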