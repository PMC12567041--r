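#' Pathway-fraction bookkeeping for total clearance
#'
#' Splits total clearance into enzyme, transporter, renal and hydrolysis
#' fractions. The UGT total estimated in vitro (assuming no biliary
#' secretion) is first reduced by the biliary (BCRP) fraction of total
#' clearance, and the revised UGT contribution is then apportioned by the
#' relative in vitro splits of the individual UGT isoforms. CYP, renal and
#' hydrolysis fractions pass through unchanged.
#'
#' @param ugt_total total UGT-mediated fraction before the biliary
#'   correction (e.g. 0.583).
#' @param bcrp_ft biliary (BCRP) fraction of total clearance (e.g. 0.311).
#' @param ugt_splits named fractions of the UGT total per isoform, summing
#'   to 1 (e.g. `c(UGT1A34 = 0.242, UGT2B7 = 0.479, UGT2B17 = 0.279)`).
#' @param cyp_fms named CYP fractions of total clearance.
#' @param fe renal fraction of total clearance.
#' @param f_hyd hydrolysis fraction of total clearance.
#' @return a `pathway_fractions` list with per-pathway fm, ft per
#'   transporter, `fe_renal`, `f_hydrolysis` and the vector `total`.
#' @export
partition_clearance <- function(ugt_total, bcrp_ft, ugt_splits, cyp_fms,
                                fe, f_hyd) {
  vals <- c(ugt_total, bcrp_ft, ugt_splits, cyp_fms, fe, f_hyd)
  check_that(all(vals >= 0 & vals <= 1), "all inputs must be fractions in [0, 1]")
  check_that(abs(sum(ugt_splits) - 1) < 1e-6, "ugt_splits must sum to 1")
  check_that(bcrp_ft <= ugt_total,
             "bcrp_ft exceeds the UGT total it is subtracted from")
  ugt_revised <- ugt_total - bcrp_ft
  fm_ugt <- ugt_revised * ugt_splits
  fm <- c(cyp_fms, fm_ugt)
  total <- sum(fm) + bcrp_ft + fe + f_hyd
  check_that(abs(total - 1) <= 0.01,
             sprintf("pathway fractions sum to %.4f, outside 1 +/- 0.01", total))
  structure(list(fm = fm, ft = c(BCRP = unname(bcrp_ft)),
                 fe_renal = fe, f_hydrolysis = f_hyd,
                 ugt_revised = ugt_revised, total = total),
            class = "pathway_fractions")
}

#' Biliary fraction of oral clearance from a with/without pair
#'
#' `ft = 1 - CL/F(without) / CL/F(with)`: the fractional contribution of a
#' transporter estimated by removing it from the model. Scale invariant.
#'
#' @param clf_with oral clearance with the transporter (L/h).
#' @param clf_without oral clearance without it (L/h).
#' @return the transported fraction `ft`.
#' @examples
#' bcrp_fraction(7.19, 4.96)   # ~0.31
#' @export
bcrp_fraction <- function(clf_with, clf_without) {
  check_that(clf_without > 0 && clf_with >= clf_without,
             "requires clf_with >= clf_without > 0")
  1 - clf_without / clf_with
}

#' Renal clearance relative to unbound glomerular filtration
#'
#' Ratio of renal clearance to `fu_plasma * GFR`. A ratio near 1 indicates
#' filtration-only elimination; well below 1 suggests reabsorption and
#' above 1 active secretion.
#'
#' @param cl_renal renal clearance (mL/min/1.73 m^2).
#' @param fu_plasma fraction unbound in plasma.
#' @param gfr glomerular filtration rate (mL/min/1.73 m^2).
#' @return dimensionless ratio.
#' @examples
#' renal_fraction_check(1.8, 0.027, 120)  # ~0.56
#' @export
renal_fraction_check <- function(cl_renal, fu_plasma, gfr) {
  check_that(all(c(cl_renal, fu_plasma, gfr) > 0), "all inputs must be positive")
  cl_renal / (fu_plasma * gfr)
}

#' Convert a clearance in mL/min to L/h
#' @param x clearance in mL/min.
#' @return clearance in L/h.
#' @export
ml_min_to_l_h <- function(x) x * 60 / 1000

# passive-diffusion clearance of the liver model for a subject (L/h)
clpd_l_h <- function(compound, subject) {
  tr <- compound$transporters[[1]]
  tr$cl_pd * subject$hepatocellularity * subject$liver_mass *
    subject$clpd_scalar * 60 / 1000
}

# hepatic plasma flow (portal + arterial), L/h
q_hepatic <- function(subject) {
  sum(subject$tissue_blood_flows[c("gut", "spleen")]) + subject$q_hepatic_arterial
}

#' Retrograde translation of pathway fractions into enzyme Vmax values
#'
#' Inverts the whole-body model at the linear (low-dose) operating point:
#' from a target oral clearance and the pathway fractions, the total
#' hepatocellular unbound intrinsic clearance is recovered through the
#' well-stirred liver and the passive-diffusion barrier, apportioned to
#' pathways by their fm, and expressed per pmol of enzyme via the
#' subject's abundance, microsomal protein and liver mass; Vmax is then
#' the product of the per-pmol intrinsic clearance and the unbound Km.
#'
#' @param fractions a [partition_clearance()] result, or a named list with
#'   `fm` (per enzyme), `ft` (per transporter), `fe_renal`, `f_hydrolysis`.
#' @param oral_clearance_target target CL/F (L/h) at the linear anchor.
#' @param km_u named unbound Km per enzyme (uM).
#' @param subject a `pbpk_subject` (the mean subject for model building).
#' @param compound the full-model `pbpk_compound` (binding, absorption and
#'   liver-model constants).
#' @return list with `vmax` (pmol/min/pmol enzyme), `clint` (L/h per
#'   pathway incl. hydrolysis and the linear-equivalent BCRP clearance),
#'   `clint_cell_total`, `fg`, `fh`, and `clpd` (L/h).
#' @export
retrograde_vmax <- function(fractions, oral_clearance_target, km_u, subject,
                            compound) {
  check_that(oral_clearance_target > 0, "oral_clearance_target must be > 0")
  check_that(all(km_u > 0), "km_u must be > 0")
  fu_p <- compound$binding$fu_plasma * subject$fu_scalar
  ab <- compound$absorption
  fg <- ab$q_gut / (ab$q_gut + ab$fu_gut *
                      qgut_clint_from_fg(compound))
  clpd <- clpd_l_h(compound, subject)
  qh <- q_hepatic(subject)
  fe <- fractions$fe_renal

  # renal clearance is carried retrogradely from its target fraction of
  # systemic clearance (fe), which keeps the pathway bookkeeping exact:
  # fu CLint_app = CL/F x fa x Fg x (1 - fe)
  x <- oral_clearance_target * ab$fa * fg * (1 - fe)
  fh <- qh / (qh + x)
  clr <- fe * oral_clearance_target * ab$fa * fg * fh
  clint_app <- x / fu_p
  check_that(clint_app < clpd,
             "required intrinsic clearance exceeds the passive-diffusion barrier")
  clint_cell <- clpd * clint_app / (clpd - clint_app)

  w <- c(fractions$fm,
         HYD = unname(fractions$f_hydrolysis),
         fractions$ft) / (1 - fe)
  clint <- clint_cell * w

  abund <- subject$enzyme_abundance
  prot <- subject$mppgl * subject$liver_mass    # mg microsomal protein
  vmax <- vapply(names(fractions$fm), function(e) {
    if (fractions$fm[[e]] == 0) return(0)
    check_that(e %in% names(abund) && abund[[e]] > 0,
               paste0("zero abundance for enzyme with fm > 0: ", e))
    clint_per_pmol <- clint[[e]] * 1e6 / 60 / prot / abund[[e]]  # uL/min/pmol
    clint_per_pmol * km_u[[e]]
  }, 0)
  list(vmax = vmax, clint = clint, clint_cell_total = clint_cell,
       fg = fg, fh = fh, clpd = clpd, fu_p = fu_p, cl_renal = clr)
}

# unbound gut-wall intrinsic clearance implied by the target Fg
qgut_clint_from_fg <- function(compound) {
  ab <- compound$absorption
  fg <- ab$fg_target %||% 0.83
  ab$q_gut * (1 / fg - 1) / ab$fu_gut
}

# the asciminib pathway-fraction set used throughout the package
asciminib_fractions <- function(compound) {
  fm <- setNames(vapply(compound$enzymes, function(e) e$fm_target, 0),
                 vapply(compound$enzymes, function(e) e$enzyme, ""))
  tr <- compound$transporters[[1]]
  list(fm = fm, ft = c(BCRP = tr$ft_target_low_dose),
       fe_renal = compound$renal$fe_target,
       f_hydrolysis = compound$additional_clearance$fm_target)
}
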