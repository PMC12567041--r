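#' Load and validate a compound parameterization
#'
#' Reads a structured compound file (YAML, schema version 1) into a
#' validated `pbpk_compound` object. Two model types exist: `"full"`
#' (whole-body PBPK with permeability-limited liver; asciminib) and
#' `"reduced"` (compartmental stand-in for perpetrator and probe drugs).
#' Units are normalized to the internal convention: concentrations in
#' micromolar, time in hours, volumes in litres.
#'
#' @param source path to a YAML file, a bare compound name resolved
#'   against the fixtures shipped under `inst/extdata/compounds`
#'   (e.g. `"asciminib"`, `"midazolam"`), or an already-parsed list.
#' @return a validated `pbpk_compound`.
#' @export
load_compound <- function(source) {
  x <- if (is.list(source)) {
    source
  } else if (file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::read_yaml(extdata_path("compounds", paste0(source, ".yaml")))
  }
  validate_compound(x)
}

#' Write a compound to a YAML file
#'
#' Serialization round trips: `load_compound(write_compound(x, f))`
#' reproduces `x`.
#'
#' @param compound a `pbpk_compound`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_compound <- function(compound, path) {
  x <- unclass(compound)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' List shipped compound fixtures
#' @return character vector of compound names.
#' @export
compound_fixtures <- function() {
  sub("[.]yaml$", "", dir(extdata_path("compounds"), pattern = "[.]yaml$"))
}

#' Validate a compound parameter list
#'
#' Checks mandatory fields, positivity/range invariants and, for the full
#' model, that the declared pathway fractions (fm per enzyme, ft per
#' transporter, renal fe and the hydrolysis fraction) sum to 1 within
#' 0.01. Errors name the offending field.
#'
#' @param x a list with the compound schema.
#' @return the list with class `pbpk_compound`.
#' @export
validate_compound <- function(x) {
  for (f in c("name", "model_type", "physchem", "binding")) {
    check_that(!is.null(x[[f]]), paste0("missing mandatory field: ", f))
  }
  mw <- x$physchem$molecular_weight
  check_that(!is.null(mw), "missing mandatory field: physchem$molecular_weight")
  check_that(is.numeric(mw) && mw > 0, "physchem$molecular_weight must be > 0")
  fu <- x$binding$fu_plasma
  check_that(!is.null(fu) && fu > 0 && fu <= 1,
             "binding$fu_plasma must be in (0, 1]")
  if (x$model_type == "full") {
    cls <- x$physchem$compound_class %||% "neutral"
    if (cls != "neutral") {
      check_that(is.finite(x$physchem$pka %||% NA_real_),
                 "physchem$pka must be finite for an ionizable compound")
    }
    check_that((x$binding$blood_to_plasma %||% 0) > 0,
               "binding$blood_to_plasma must be > 0")
    ab <- x$absorption
    check_that(!is.null(ab), "missing mandatory field: absorption")
    check_that(ab$fa > 0 && ab$fa <= 1, "absorption$fa must be in (0, 1]")
    check_that(ab$ka > 0, "absorption$ka must be > 0")
    check_that((ab$tlag %||% 0) >= 0, "absorption$tlag must be >= 0")
    check_that(ab$fu_gut > 0 && ab$fu_gut <= 1,
               "absorption$fu_gut must be in (0, 1]")
    check_that(ab$q_gut > 0, "absorption$q_gut must be > 0")
    ds <- x$distribution
    check_that(ds$kp_scalar > 0, "distribution$kp_scalar must be > 0")
    check_that(ds$vss_target > 0, "distribution$vss_target must be > 0")
    for (e in x$enzymes) {
      lbl <- paste0("enzymes[", e$enzyme, "]")
      check_that(e$vmax >= 0, paste0(lbl, "$vmax must be >= 0"))
      check_that(e$km_u > 0, paste0(lbl, "$km_u must be > 0"))
      check_that(e$fu_mic > 0 && e$fu_mic <= 1,
                 paste0(lbl, "$fu_mic must be in (0, 1]"))
      check_that(e$fm_target >= 0 && e$fm_target <= 1,
                 paste0(lbl, "$fm_target must be in [0, 1]"))
    }
    for (tr in x$transporters) {
      lbl <- paste0("transporters[", tr$transporter, "]")
      check_that(tr$jmax >= 0, paste0(lbl, "$jmax must be >= 0"))
      check_that(tr$km > 0, paste0(lbl, "$km must be > 0"))
      check_that(tr$cl_pd > 0, paste0(lbl, "$cl_pd must be > 0"))
    }
    check_that((x$renal$cl_renal %||% -1) >= 0, "renal$cl_renal must be >= 0")
    check_that((x$additional_clearance$hlm_clint_u %||% -1) >= 0,
               "additional_clearance$hlm_clint_u must be >= 0")
    tot <- sum(vapply(x$enzymes, function(e) e$fm_target, 0)) +
      sum(vapply(x$transporters, function(t) t$ft_target_low_dose %||% 0, 0)) +
      x$renal$fe_target + x$additional_clearance$fm_target
    check_that(abs(tot - 1) <= 0.01,
               sprintf("pathway fm/ft/fe targets sum to %.4f, not 1 +/- 0.01", tot))
  } else if (x$model_type == "reduced") {
    pk <- x$pk
    check_that(!is.null(pk), "missing mandatory field: pk")
    for (f in c("ka", "vc", "clint_u_h")) {
      check_that((pk[[f]] %||% -1) >= 0, paste0("pk$", f, " must be >= 0"))
    }
    fms <- vapply(x$pathways, function(p) p$fm, 0)
    check_that(all(fms >= 0) && sum(fms) <= 1 + 1e-9,
               "pathway fm values must be fractions summing to <= 1")
  } else {
    stop_field(paste0("unknown model_type: ", x$model_type))
  }
  for (ih in x$inhibition) {
    check_that(ih$ki_u > 0, paste0("inhibition[", ih$target, "]$ki_u must be > 0"))
  }
  for (ind in x$induction) {
    check_that(ind$indc50 > 0,
               paste0("induction[", ind$target, "]$indc50 must be > 0"))
    check_that(ind$indmax >= 1,
               paste0("induction[", ind$target, "]$indmax must be >= 1"))
  }
  structure(x, class = "pbpk_compound")
}

#' @export
print.pbpk_compound <- function(x, ...) {
  cat(sprintf("<pbpk_compound> %s (%s model)\n", x$name, x$model_type))
  invisible(x)
}

#' Convert an unbound IC50 to an unbound Ki
#'
#' Three conventions are supported: `"half"` (competitive inhibition with
#' probe substrate at its Km, Ki = IC50/2), `"substrate-corrected"`
#' (Cheng-Prusoff, Ki = IC50 / (1 + S/Km_probe)) and `"direct"`
#' (Ki = IC50).
#'
#' @param ic50_u unbound IC50 (uM), > 0.
#' @param conversion one of `"half"`, `"substrate-corrected"`, `"direct"`.
#' @param S probe substrate concentration (uM), substrate-corrected mode.
#' @param km_probe probe substrate Km (uM), substrate-corrected mode.
#' @return unbound Ki (uM).
#' @examples
#' ki_from_ic50(20.8, "half")                                   # 10.4
#' ki_from_ic50(0.56, "substrate-corrected", S = 10, km_probe = 16.8)
#' @export
ki_from_ic50 <- function(ic50_u, conversion = c("half", "substrate-corrected",
                                                "direct"),
                         S = 0, km_probe = NULL) {
  conversion <- match.arg(conversion)
  check_that(is.numeric(ic50_u) && all(ic50_u > 0), "ic50_u must be > 0")
  switch(conversion,
         half = ic50_u / 2,
         direct = ic50_u,
         `substrate-corrected` = {
           check_that(all(S >= 0), "S must be >= 0")
           check_that(!is.null(km_probe) && all(km_probe > 0),
                      "km_probe must be > 0")
           ic50_u / (1 + S / km_probe)
         })
}

#' Unbound Michaelis constant from the apparent value
#'
#' `Km_u = Km_apparent * fu_mic`, correcting for non-specific binding to
#' microsomal protein in the incubation.
#'
#' @param km_apparent apparent Km (uM).
#' @param fu_mic fraction unbound in the microsomal incubation, in (0, 1].
#' @return unbound Km (uM).
#' @export
km_unbound <- function(km_apparent, fu_mic) {
  check_that(all(fu_mic > 0) && all(fu_mic <= 1), "fu_mic must be in (0, 1]")
  km_apparent * fu_mic
}
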