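# ---- predictive-performance statistics ------------------------------------

#' Percent prediction error
#'
#' `%PE = (predicted - observed) / observed x 100`.
#'
#' @param predicted,observed numeric vectors; `observed` must be > 0.
#' @return signed percent error.
#' @export
percent_pe <- function(predicted, observed) {
  check_that(all(observed > 0), "observed values must be > 0")
  (predicted - observed) / observed * 100
}

drop_nonpositive <- function(predicted, observed) {
  bad <- !(predicted > 0 & observed > 0) | !is.finite(predicted) |
    !is.finite(observed)
  if (any(bad)) {
    warning(sum(bad), " non-positive pairs excluded", call. = FALSE)
  }
  list(p = predicted[!bad], o = observed[!bad])
}

#' Average and absolute average fold error
#'
#' `AFE = 10^mean(log10(pred/obs))` (bias; > 1 over-, < 1 underprediction)
#' and `AAFE = 10^mean(|log10(pred/obs)|)` (absolute accuracy; <= 2 is the
#' usual success bound).
#'
#' @param predicted,observed numeric vectors of PK parameter values.
#' @return named vector `c(afe, aafe)`.
#' @export
afe_aafe <- function(predicted, observed) {
  check_that(length(predicted) > 0 && length(predicted) == length(observed),
             "need a non-empty set of prediction pairs")
  z <- drop_nonpositive(predicted, observed)
  lr <- log10(z$p / z$o)
  c(afe = 10^mean(lr), aafe = 10^mean(abs(lr)))
}

#' Geometric mean fold error of ratio predictions
#'
#' Identical in form to the AAFE, conventionally reported for
#' interaction and organ-impairment ratios:
#' `GMFE = 10^mean(|log10(pred_ratio/obs_ratio)|)`.
#'
#' @param predicted_ratio,observed_ratio numeric ratio vectors.
#' @return the GMFE.
#' @export
gmfe <- function(predicted_ratio, observed_ratio) {
  unname(afe_aafe(predicted_ratio, observed_ratio)["aafe"])
}

#' Observed-ratio-dependent acceptance limits (Guest criteria)
#'
#' For an observed interaction ratio `R` (oriented so `R' = max(R, 1/R)`),
#' the acceptance half-width is `L = (delta + 2 (R' - 1)) / R'` with
#' `delta = 1` at zero variability and `delta = 1/(1 - CV/100)` when an
#' intra-subject variability term is included (1.25 at the 20% CV carried
#' through the verification); the limits are `R / L` and `R x L`, giving
#' the classical [0.8, 1.25] near R = 1 at that variability and widening
#' toward twofold for large interactions. The intervals for `R` and `1/R`
#' are reciprocal.
#'
#' @param observed_ratio observed geometric mean ratio (> 0).
#' @param intra_subject_cv intra-subject variability in percent
#'   (default 0; 20 gives delta = 1.25).
#' @return named vector `c(lower, upper)`.
#' @export
guest_limits <- function(observed_ratio, intra_subject_cv = 0) {
  check_that(observed_ratio > 0, "observed_ratio must be > 0")
  check_that(intra_subject_cv < 100, "intra_subject_cv must be below 100")
  delta <- 1 / (1 - intra_subject_cv / 100)
  rp <- max(observed_ratio, 1 / observed_ratio)
  L <- (delta + 2 * (rp - 1)) / rp
  c(lower = observed_ratio / L, upper = observed_ratio * L)
}

#' Flag a predicted ratio against the Guest limits
#' @param predicted_ratio predicted geometric mean ratio.
#' @inheritParams guest_limits
#' @return logical; `TRUE` when inside the limits.
#' @export
guest_flag <- function(predicted_ratio, observed_ratio, intra_subject_cv = 0) {
  lim <- guest_limits(observed_ratio, intra_subject_cv)
  predicted_ratio >= lim["lower"] & predicted_ratio <= lim["upper"]
}

#' Twofold and 25% prediction-accuracy flags
#'
#' Flags each predicted/observed ratio `R_pred/obs` against the twofold
#' rule (`|log10 R| < 0.301`) and the stricter 25% deviation
#' (`|log10 R| < 0.097`).
#'
#' @param predicted,observed numeric vectors.
#' @return data frame with `r_pred_obs`, `within_twofold`, `within_25pct`.
#' @export
bounds_checks <- function(predicted, observed) {
  r <- predicted / observed
  lr <- log10(r)
  data.frame(r_pred_obs = r,
             within_twofold = abs(lr) < 0.301,
             within_25pct = abs(lr) < 0.097)
}

#' Full evaluation report for a set of prediction pairs
#'
#' Per-pair percent prediction error, predicted/observed ratio and bound
#' flags, plus the AFE/AAFE (or GMFE) summary.
#'
#' @param predicted,observed numeric vectors.
#' @param label optional labels.
#' @param metric metric name stored in the output.
#' @return an `evaluation_report` list with `pairs` and `summary`.
#' @export
evaluation_report <- function(predicted, observed, label = NULL,
                              metric = "value") {
  pairs <- data.frame(label = label %||% seq_along(predicted),
                      metric = metric, predicted = predicted,
                      observed = observed,
                      pe = percent_pe(predicted, observed))
  pairs <- cbind(pairs, bounds_checks(predicted, observed))
  s <- afe_aafe(predicted, observed)
  structure(list(pairs = pairs,
                 summary = data.frame(metric = metric, n = nrow(pairs),
                                      afe = s["afe"], aafe = s["aafe"])),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: n = %d, AFE %.3f, AAFE %.3f\n",
              x$summary$metric, x$summary$n, x$summary$afe, x$summary$aafe))
  invisible(x)
}

#' Reference PK-summary table (transcribed printed values)
#'
#' Observed and platform-simulated Cmax, AUC, Ctrough and Tmax of
#' asciminib after single 40 mg doses in healthy volunteers and multiple
#' 20-200 mg doses in cancer patients, as printed; used by the evaluation
#' harness.
#'
#' @return data frame.
#' @export
table2_pk_reference <- function() {
  read.delim(extdata_path("table2_pk_summary.tsv"))
}

#' Reference DDI / organ-impairment ratio table (transcribed printed
#' values)
#' @return data frame of the 11 verification studies.
#' @export
table3_ratio_reference <- function() {
  read.delim(extdata_path("table3_ddi_oi.tsv"))
}
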