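#' Noncompartmental PK metrics from a simulated profile
#'
#' Standard summaries over a dosing interval: Cmax, Tmax (relative to the
#' interval start), the trough concentration at the end of the interval,
#' AUC over the interval (linear-up/log-down trapezoid) and, for single
#' doses, AUC extrapolated to infinity from a terminal log-linear
#' regression. The extrapolated fraction is reported; when the terminal
#' slope is not estimable, `auc_inf` is `NA` and the profile is flagged.
#'
#' @param profile a `concentration_profile` (or data frame with a `time`
#'   column).
#' @param compound column name of the analyte.
#' @param start interval start time (h), e.g. the last dose time.
#' @param tau dosing interval (h); `Inf` extrapolates to infinity.
#' @return a one-row data frame: `auc_tau`, `auc_inf`, `cmax`, `tmax`,
#'   `ctrough`, `kz`, `extrap_frac`, `flag_terminal`.
#' @export
pk_metrics <- function(profile, compound, start = 0, tau = Inf) {
  tt <- profile$time
  cc <- profile[[compound]]
  check_that(!is.null(cc), paste0("no column for compound: ", compound))
  idx <- tt >= start & (is.finite(tau) & tt <= start + tau | !is.finite(tau))
  t0 <- tt[idx] - start
  c0 <- cc[idx]
  check_that(length(t0) > 2, "profile does not cover the requested interval")
  cmax <- max(c0)
  tmax <- t0[which.max(c0)]
  auc_tau <- auc_trapz(t0, c0)
  ctrough <- c0[length(c0)]

  auc_inf <- NA_real_
  kz <- NA_real_
  extrap <- NA_real_
  flag <- FALSE
  # terminal slope: log-linear fit over the last third of the profile
  # after Tmax (at least 4 points, positive concentrations)
  sel <- which(t0 > tmax & t0 >= t0[length(t0)] * 2 / 3 & c0 > 0)
  if (length(sel) >= 4) {
    fit <- lm(log(c0[sel]) ~ t0[sel])
    kz <- -coef(fit)[[2]]
    if (is.finite(kz) && kz > 1e-6) {
      tail_auc <- ctrough / kz
      auc_inf <- auc_tau + tail_auc
      extrap <- tail_auc / auc_inf
    } else {
      flag <- TRUE
    }
  } else {
    flag <- TRUE
  }
  data.frame(auc_tau = auc_tau, auc_inf = auc_inf, cmax = cmax, tmax = tmax,
             ctrough = ctrough, kz = kz, extrap_frac = extrap,
             flag_terminal = flag)
}
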