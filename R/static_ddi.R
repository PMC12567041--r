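# ---- mechanistic-static DDI assessment ------------------------------------

# villous (enterocyte) blood flow used by the static gut term, L/h
Q_ENTEROCYTE <- 18

#' Perpetrator concentrations for the static assessment
#'
#' Simulates the perpetrator (asciminib) to steady state in the mean
#' healthy subject and extracts the concentrations the mechanistic-static
#' equations use: unbound maximal systemic concentration, unbound hepatic
#' inlet maximum `fu (Cmax + Fa ka D / Q_h,blood)` and the gut
#' concentration `fu_gut Fa ka D / Q_ent`.
#'
#' @param model the `victim_model` acting as perpetrator.
#' @param dose_mg dose (mg).
#' @param interval dosing interval label (see [regimen()]).
#' @param days days to steady state.
#' @return list with `imax_u_plasma`, `imax_u_inlet`, `igut_u` (uM) and
#'   `cmax_ng_ml`.
#' @export
static_concentrations <- function(model, dose_mg, interval = "BID",
                                  days = 5) {
  cmp <- model$compound
  ms <- mean_subject()
  sys <- build_system(model, list(), ms)
  rg <- regimen(dose_mg, interval, n_days = days)
  prof <- simulate_profile(sys, rg, duration = days * 24)
  idx <- prof$time >= last_dose_time(rg)
  cmax <- max(prof[[cmp$name]][idx])                    # ng/mL
  cmax_um <- cmax / cmp$physchem$molecular_weight
  fu <- cmp$binding$fu_plasma
  ab <- cmp$absorption
  d_umol <- dose_mg * 1000 / cmp$physchem$molecular_weight
  qh_blood <- q_hepatic(ms) / (1 - ms$hematocrit)
  inlet <- cmax_um + ab$fa * ab$ka * d_umol / qh_blood
  list(imax_u_plasma = fu * cmax_um,
       imax_u_inlet = fu * inlet,
       igut_u = ab$fu_gut * ab$fa * ab$ka * d_umol / Q_ENTEROCYTE,
       cmax_ng_ml = cmax)
}

#' Mechanistic-static (Net Effect) AUC ratio
#'
#' For an orally dosed probe substrate,
#' `AUCR = 1 / ((Ag Bg Cg)(1 - Fg) + Fg) x 1 / (sum_e fm_e Ah_e Bh_e Ch_e + 1 - sum fm)`
#' with `A = 1/(1 + I/Ki)` the reversible term, `B` the time-dependent
#' inactivation term (unity when absent) and `C = 1 + d Emax I/(IndC50 + I)`
#' the induction term; gut terms use the gut concentration, hepatic terms
#' the unbound inlet maximum.
#'
#' @param input list with `imax_u_inlet`, `igut_u` (from
#'   [static_concentrations()]), `ki_u` (named by enzyme), optional
#'   `induction` (named list per enzyme: `indc50`, `emax`), optional `d`
#'   (induction scaling, default 1).
#' @param probe list describing the substrate: `pathways` (named fm per
#'   enzyme), `fg`, `gut_enzyme` (or `"none"`).
#' @return the predicted fold-change in the probe's AUC.
#' @export
net_effect_aucr <- function(input, probe) {
  d <- input$d %||% 1
  fm <- probe$pathways
  check_that(all(fm >= 0) && sum(fm) <= 1 + 1e-9, "probe fm must sum to <= 1")
  term <- function(enzyme, I) {
    A <- if (!is.null(input$ki_u[[enzyme]])) 1 / (1 + I / input$ki_u[[enzyme]]) else 1
    Cind <- if (!is.null(input$induction[[enzyme]])) {
      ind <- input$induction[[enzyme]]
      1 + d * ind$emax * I / (ind$indc50 + I)
    } else 1
    A * Cind
  }
  hep <- sum(vapply(names(fm), function(e) {
    fm[[e]] * term(e, input$imax_u_inlet)
  }, 0)) + 1 - sum(fm)
  check_that(hep > 0, "hepatic net-effect term collapsed to zero")
  gut <- 1
  ge <- probe$gut_enzyme %||% "none"
  fg <- probe$fg %||% 1
  if (!identical(ge, "none") && fg < 1) {
    gut <- term(ge, input$igut_u) * (1 - fg) + fg
  }
  (1 / gut) * (1 / hep)
}

#' Basic static induction risk (R3)
#'
#' `R3 = 1 / (1 + d (Indmax - 1) I / (IndC50 + I))`; values below the
#' guidance cutoff (0.8) flag induction risk.
#'
#' @param I perpetrator concentration (uM).
#' @param indc50 induction EC50 (uM).
#' @param indmax maximal fold induction (>= 1).
#' @param d scaling factor (default 1).
#' @return R3 in (0, 1].
#' @export
r3 <- function(I, indc50, indmax, d = 1) {
  check_that(all(c(I, indc50) >= 0) && indmax >= 1 && d > 0,
             "inputs must be positive and indmax >= 1")
  1 / (1 + d * (indmax - 1) * I / (indc50 + I))
}

#' Relative induction score
#'
#' `RIS = Emax I_u / (EC50 + I_u)` with the in vitro induction parameters
#' and the unbound steady-state maximal concentration.
#'
#' @param emax in vitro maximal fold increase (Emax = Indmax - 1).
#' @param ec50 in vitro EC50 (uM).
#' @param i_u unbound perpetrator concentration (uM).
#' @return the relative induction score.
#' @export
ris <- function(emax, ec50, i_u) {
  check_that(all(c(emax, ec50) > 0) && all(i_u >= 0), "inputs must be positive")
  emax * i_u / (ec50 + i_u)
}

# documented mapping of RIS to the predicted AUC reduction of a sensitive
# CYP3A substrate (calibration-curve slope constant)
RIS_SLOPE <- 2.3

#' AUC reduction implied by a relative induction score
#' @param score a [ris()] value.
#' @return predicted fractional AUC reduction of a sensitive substrate.
#' @export
ris_auc_reduction <- function(score) 1 - 1 / (1 + RIS_SLOPE * score)

#' Rifampicin induction calibration reference
#'
#' In vitro reference pair as printed (EC50 0.42 uM, Emax 124) and the
#' implied in vivo reference back-solved from the calibrated asciminib
#' CYP3A4 pair (2.7 -> 2.057 uM, Emax 4.4 -> 0.53).
#'
#' @return list with `invitro` and `invivo` induction parameter lists.
#' @export
rifampicin_reference <- function() {
  list(invitro = list(indc50 = 0.42, indmax = 125, emax = 124),
       invivo = list(indc50 = 0.42 * 2.057 / 2.7,
                     indmax = 1 + 124 * (0.53 / 4.4),
                     emax = 124 * (0.53 / 4.4)))
}

#' Calibrate in vitro induction parameters against a reference inducer
#'
#' Scales a test compound's in vitro induction parameters by the in vivo
#' to in vitro ratio of a reference inducer:
#' `IndC50_cal = IndC50_test x EC50_ref,vivo / EC50_ref,vitro`,
#' `Emax_cal = Emax_test x Emax_ref,vivo / Emax_ref,vitro`,
#' `Indmax_cal = Emax_cal + 1`. Identity when the reference in vivo
#' equals the reference in vitro.
#'
#' @param test_invitro list with `indc50` and `indmax` (or `emax`).
#' @param ref_invitro,ref_invivo reference parameter lists.
#' @return calibrated list with `indc50`, `indmax`, `emax`,
#'   `calibrated = TRUE`.
#' @export
calibrate_induction <- function(test_invitro,
                                ref_invitro = rifampicin_reference()$invitro,
                                ref_invivo = rifampicin_reference()$invivo) {
  ex <- function(x) x$emax %||% (x$indmax - 1)
  check_that(ref_invitro$indc50 > 0 && ex(ref_invitro) > 0 &&
               ref_invivo$indc50 > 0 && ex(ref_invivo) > 0,
             "reference induction parameters must be positive")
  emax_cal <- ex(test_invitro) * ex(ref_invivo) / ex(ref_invitro)
  list(indc50 = test_invitro$indc50 * ref_invivo$indc50 / ref_invitro$indc50,
       emax = emax_cal, indmax = emax_cal + 1, calibrated = TRUE)
}

# default probe substrate definitions for the static flag table
STATIC_PROBES <- list(
  CYP3A4 = list(pathways = c(CYP3A4 = 0.94), fg = 0.57, gut_enzyme = "CYP3A4"),
  CYP2C9 = list(pathways = c(CYP2C9 = 0.91), fg = 1, gut_enzyme = "none"),
  CYP2C8 = list(pathways = c(CYP2C8 = 0.63, CYP3A4 = 0.25), fg = 0.87,
                gut_enzyme = "CYP3A4"),
  CYP2C19 = list(pathways = c(CYP2C19 = 0.87, CYP3A4 = 0.10), fg = 0.95,
                 gut_enzyme = "CYP3A4"),
  CYP1A2 = list(pathways = c(CYP1A2 = 0.95), fg = 1, gut_enzyme = "none"),
  UGT1A1 = list(pathways = c(UGT1A1 = 0.91), fg = 1, gut_enzyme = "none")
)

#' Static DDI risk-assessment table
#'
#' Net Effect AUC ratios for sensitive probe substrates of the enzymes
#' asciminib inhibits, plus R3 and RIS for the induced enzymes, with
#' flags against the 0.8 / 1.25 no-effect bounds. The flag table uses the
#' in vitro inhibition constants (the convention under which these risk
#' flags are generated prospectively); the ODE engine retains the final
#' optimized values.
#'
#' @param model the `victim_model` as perpetrator.
#' @param dose_mg dose (mg).
#' @param interval dosing interval label.
#' @param include_induction include induction terms in the Net Effect
#'   equation (default `FALSE`, inhibition-only flags).
#' @param conc optionally precomputed [static_concentrations()].
#' @return data frame: enzyme, mechanism, value, flag.
#' @export
static_flags <- function(model, dose_mg = 40, interval = "BID",
                         include_induction = FALSE, conc = NULL) {
  cmp <- model$compound
  conc <- conc %||% static_concentrations(model, dose_mg, interval)
  ki <- list()
  for (x in cmp$inhibition) ki[[x$target]] <- x$ki_u_invitro %||% x$ki_u
  ind <- list()
  if (include_induction) {
    for (x in cmp$induction) {
      ind[[x$target]] <- list(indc50 = x$indc50, emax = x$indmax - 1)
    }
  }
  input <- c(conc, list(ki_u = ki, induction = ind))
  rows <- lapply(names(STATIC_PROBES), function(e) {
    aucr <- net_effect_aucr(input, STATIC_PROBES[[e]])
    data.frame(enzyme = e, mechanism = "net_effect", value = aucr,
               flag = aucr > 1.25 | aucr < 0.8)
  })
  for (x in cmp$induction) {
    v <- r3(conc$imax_u_plasma, x$indc50, x$indmax)
    rows[[length(rows) + 1]] <- data.frame(
      enzyme = x$target, mechanism = "R3", value = v, flag = v < 0.8)
    s <- ris(x$indmax - 1, x$indc50, conc$imax_u_plasma)
    rows[[length(rows) + 1]] <- data.frame(
      enzyme = x$target, mechanism = "RIS", value = s,
      flag = ris_auc_reduction(s) > 0.2)
  }
  do.call(rbind, rows)
}
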