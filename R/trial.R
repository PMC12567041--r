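# ---- virtual clinical-trial layer -----------------------------------------

#' Define a dosing regimen
#'
#' @param dose dose in mg (> 0).
#' @param interval `"QD"`, `"BID"`, `"TID"`, `"QID"` or `"single"`.
#' @param n_days number of dosing days (>= 1; ignored for `"single"`).
#' @param start_day first dosing day (day 1 = time 0).
#' @param offset_h additional offset (h) of every dose within the day,
#'   e.g. a probe dosed 1 h after the perpetrator.
#' @return a `regimen` object.
#' @export
regimen <- function(dose, interval = c("BID", "QD", "TID", "QID", "single"),
                    n_days = 1, start_day = 1, offset_h = 0) {
  interval <- match.arg(interval)
  check_that(dose > 0, "dose must be > 0")
  check_that(n_days >= 1, "n_days must be >= 1")
  structure(list(dose = dose, interval = interval, n_days = n_days,
                 start_day = start_day, offset_h = offset_h),
            class = "regimen")
}

regimen_times <- function(rg) {
  t0 <- (rg$start_day - 1) * 24 + rg$offset_h
  if (rg$interval == "single") return(t0)
  tau <- c(QD = 24, BID = 12, TID = 8, QID = 6)[[rg$interval]]
  t0 + seq(0, rg$n_days * 24 - tau, by = tau)
}

regimen_tau <- function(rg) {
  if (rg$interval == "single") Inf
  else c(QD = 24, BID = 12, TID = 8, QID = 6)[[rg$interval]]
}

last_dose_time <- function(rg) tail(regimen_times(rg), 1)

#' Define a virtual trial
#'
#' A trial couples one or more dosing regimens (by compound name) with a
#' virtual population and a replication structure. The `analyte` is the
#' compound whose PK is measured; the control arm repeats the simulation
#' with every non-analyte regimen removed, in the same subjects
#' (within-subject pairing, mirroring crossover designs).
#'
#' @param regimens named list of [regimen()]s, names = compound names.
#' @param analyte name of the measured compound.
#' @param population a [population_spec()].
#' @param n_trials,n_subjects replication structure (default 10 x 10).
#' @param seed integer seed.
#' @return a `trial_design` object.
#' @export
trial_design <- function(regimens, analyte, population = population_spec(),
                         n_trials = 10, n_subjects = 10, seed = 1) {
  check_that(n_trials >= 1 && n_subjects >= 1,
             "n_trials and n_subjects must be >= 1")
  check_that(analyte %in% names(regimens), "analyte must have a regimen")
  structure(list(regimens = regimens, analyte = analyte,
                 population = population, n_trials = n_trials,
                 n_subjects = n_subjects, seed = seed),
            class = "trial_design")
}

# absorption-parameter between-subject variability of the full compound
sample_bsv <- function(compound, n) {
  ab <- compound$absorption
  data.frame(
    ka = rlnorm_cv(n, 1, ab$ka_cv %||% 0),
    fa = rlnorm_cv(n, 1, ab$fa_cv %||% 0),
    tlag = rlnorm_cv(n, 1, ab$tlag_cv %||% 0),
    q_gut = rlnorm_cv(n, 1, ab$q_gut_cv %||% 0)
  )
}

#' Run a virtual trial
#'
#' Simulates every subject in both arms (with and without the non-analyte
#' regimens, identical physiology and absorption variability) and returns
#' per-subject PK metrics of the analyte over its last dosing interval
#' (single dose: AUC extrapolated to infinity).
#'
#' @param design a [trial_design()].
#' @param victim the full-model `victim_model` (asciminib); `NULL` for
#'   probe-only designs.
#' @param perpetrators list of reduced compounds (or names) to include.
#' @param options engine options forwarded to [build_system()].
#' @param washout_h post-last-dose simulation time for the analyte (h).
#' @param dt_out output grid (h).
#' @param subjects optionally a pre-sampled subject list (e.g. an
#'   impairment cohort); overrides the design population.
#' @param control_options engine options for the control arm when they
#'   differ (e.g. a different unbound fraction for the impaired arm).
#' @return a `trial_result` with elements `metrics` (per subject x arm)
#'   and `design`.
#' @export
run_trial <- function(design, victim = asciminib_model(),
                      perpetrators = list(), options = list(),
                      washout_h = 96, dt_out = 0.25, subjects = NULL,
                      control_options = NULL) {
  perpetrators <- lapply(perpetrators, function(p) {
    if (is.character(p)) load_compound(p) else p
  })
  n <- design$n_trials * design$n_subjects
  if (is.null(subjects)) {
    subjects <- sample_population(design$population, n, design$seed)
  }
  vic_name <- if (!is.null(victim)) victim$compound$name else "none"
  bsv <- if (!is.null(victim)) {
    with_seed(design$seed + 7L, sample_bsv(victim$compound, n))
  } else NULL

  red_names <- vapply(perpetrators, function(p) p$name, "")
  an <- design$analyte
  an_rg <- design$regimens[[an]]
  t_start <- last_dose_time(an_rg)
  tau <- regimen_tau(an_rg)
  duration <- max(vapply(design$regimens, function(r) {
    tail(regimen_times(r), 1) + regimen_tau_finite(r)
  }, 0)) |> max(t_start + ifelse(is.finite(tau), tau, washout_h))
  duration <- max(duration, t_start + washout_h * !is.finite(tau))

  arms <- list(
    treated = design$regimens,
    control = design$regimens[an]
  )
  res <- list()
  for (i in seq_len(n)) {
    opt <- options
    if (!is.null(bsv)) opt$bsv <- as.list(bsv[i, ])
    sys <- build_system(victim, perpetrators, subjects[[i]], opt)
    sys_c <- if (is.null(control_options)) sys else {
      optc <- modifyList(opt, control_options)
      build_system(victim, perpetrators, subjects[[i]], optc)
    }
    for (arm in names(arms)) {
      rgs <- arms[[arm]]
      vrg <- rgs[[vic_name]]
      prg <- lapply(red_names, function(nm) rgs[[nm]])
      prof <- simulate_profile(if (arm == "control") sys_c else sys,
                               victim_regimen = vrg, perp_regimens = prg,
                               duration = duration, dt_out = dt_out)
      m <- pk_metrics(prof, an, start = t_start,
                      tau = if (is.finite(tau)) tau else Inf)
      m$subject <- i
      m$trial <- (i - 1) %/% design$n_subjects + 1
      m$arm <- arm
      res[[length(res) + 1]] <- m
    }
  }
  structure(list(metrics = do.call(rbind, res), design = design),
            class = "trial_result")
}

regimen_tau_finite <- function(r) {
  tau <- regimen_tau(r)
  if (is.finite(tau)) tau else 0
}

#' Population PK summary of a trial arm
#'
#' Arithmetic mean, SD and CV% for AUC, Cmax and Ctrough; median and
#' range for Tmax.
#'
#' @param result a `trial_result`.
#' @param arm `"treated"` or `"control"`.
#' @return a one-row data frame.
#' @export
trial_summary <- function(result, arm = "treated") {
  m <- result$metrics[result$metrics$arm == arm, ]
  auc <- if (all(is.finite(m$auc_inf))) m$auc_inf else m$auc_tau
  s <- function(x) c(mean = mean(x), sd = sd(x), cv = 100 * sd(x) / mean(x))
  data.frame(
    n = nrow(m),
    cmax_mean = s(m$cmax)[1], cmax_sd = s(m$cmax)[2], cmax_cv = s(m$cmax)[3],
    auc_mean = s(auc)[1], auc_sd = s(auc)[2], auc_cv = s(auc)[3],
    ctrough_mean = mean(m$ctrough),
    tmax_median = median(m$tmax), tmax_min = min(m$tmax), tmax_max = max(m$tmax)
  )
}

#' Geometric mean ratio with 90% confidence interval
#'
#' Treated-to-control ratio of a PK metric. With pairing, the ratio is
#' computed per subject and the CI comes from the t distribution on the
#' log ratios; unpaired arms use the difference of log means with a
#' pooled variance. Non-positive metric values are excluded with a
#' warning.
#'
#' @param treated,control numeric metric vectors, or a `trial_result`
#'   (then `metric` selects the column and the two arms are used).
#' @param paired logical.
#' @param metric metric column when a `trial_result` is given
#'   (`"auc_inf"`, `"auc_tau"`, `"cmax"`, ...).
#' @param level confidence level (default 0.90).
#' @return a `ratio_result` list: `gmr`, `ci`, `metric`, `n`.
#' @export
ddi_ratio <- function(treated, control = NULL, paired = TRUE,
                      metric = "auc_inf", level = 0.90) {
  if (inherits(treated, "trial_result")) {
    m <- treated$metrics
    x <- m[[metric]][m$arm == "treated"]
    y <- m[[metric]][m$arm == "control"]
  } else {
    x <- treated
    y <- control
  }
  bad <- !(x > 0) | !(y > 0) | !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    warning(sum(bad), " non-positive/non-finite pairs excluded", call. = FALSE)
    if (paired) {
      x <- x[!bad]; y <- y[!bad]
    } else {
      x <- x[x > 0 & is.finite(x)]; y <- y[y > 0 & is.finite(y)]
    }
  }
  a <- (1 - level) / 2
  if (paired) {
    lr <- log(x) - log(y)
    n <- length(lr)
    se <- sd(lr) / sqrt(n)
    if (!is.finite(se)) se <- 0
    q <- if (n > 1) qt(1 - a, n - 1) else 0
    ci <- exp(mean(lr) + c(-1, 1) * q * se)
    gmr <- exp(mean(lr))
  } else {
    n <- min(length(x), length(y))
    d <- mean(log(x)) - mean(log(y))
    se <- sqrt(var(log(x)) / length(x) + var(log(y)) / length(y))
    q <- qt(1 - a, length(x) + length(y) - 2)
    ci <- exp(d + c(-1, 1) * q * se)
    gmr <- exp(d)
  }
  structure(list(gmr = gmr, ci = ci, metric = metric, n = n),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("%s geometric mean ratio %.3f (90%% CI %.3f, %.3f), n = %d\n",
              x$metric, x$gmr, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' @importFrom stats var
NULL

#' Organ-impairment study
#'
#' Simulates a single oral dose in an impaired cohort and in a
#' demographically matched healthy control cohort (same seed, impairment
#' modifiers applied to the same sampled individuals) and returns the
#' impaired-to-control geometric mean ratios for AUC(0-inf) and Cmax.
#' For severe renal impairment the sensitivity-adjusted unbound plasma
#' fraction of the compound file is applied in the impaired arm.
#'
#' @param impairment impairment label (see [population_spec()]).
#' @param dose single oral dose in mg.
#' @param model the `victim_model`.
#' @param n_trials,n_subjects replication structure.
#' @param seed integer seed.
#' @param use_adjusted_fu logical; apply `fu_plasma_renal_impaired` in the
#'   severe-RI arm (default `TRUE`).
#' @return list with `auc` and `cmax` [ddi_ratio()] results and the two
#'   per-subject metric tables.
#' @export
oi_study <- function(impairment, dose, model = asciminib_model(),
                     n_trials = 10, n_subjects = 10, seed = 1,
                     use_adjusted_fu = TRUE) {
  n <- n_trials * n_subjects
  spec_h <- population_spec("healthy", "none")
  healthy <- sample_population(spec_h, n, seed)
  impaired <- lapply(healthy, apply_impairment, impairment = impairment)
  bsv <- with_seed(seed + 7L, sample_bsv(model$compound, n))
  opt_i <- list()
  if (identical(impairment, "RI-severe") && use_adjusted_fu &&
      !is.null(model$compound$binding$fu_plasma_renal_impaired)) {
    opt_i$fu_plasma <- model$compound$binding$fu_plasma_renal_impaired
  }
  one <- function(subjects, opt) {
    res <- lapply(seq_len(n), function(i) {
      o <- opt
      o$bsv <- as.list(bsv[i, ])
      sys <- build_system(model, list(), subjects[[i]], o)
      prof <- simulate_profile(sys, regimen(dose, "single"),
                               duration = 120, dt_out = 0.25)
      pk_metrics(prof, model$compound$name, start = 0, tau = Inf)
    })
    do.call(rbind, res)
  }
  mi <- one(impaired, opt_i)
  mh <- one(healthy, list())
  list(auc = ddi_ratio(mi$auc_inf, mh$auc_inf, paired = TRUE, metric = "auc_inf"),
       cmax = ddi_ratio(mi$cmax, mh$cmax, paired = TRUE, metric = "cmax"),
       impaired = mi, control = mh)
}
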