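#' Evaluate an expression with a local random seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's random
#' state afterwards, so sampling is reproducible without touching global
#' state ("strand-free" sampling).
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# log-normal deviate with arithmetic mean `m` and CV% `cv`
rlnorm_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + (cv / 100)^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# path to an installed extdata file
extdata_path <- function(...) {
  p <- system.file("extdata", ..., package = "ascipbpk")
  if (!nzchar(p)) stop("extdata file not found: ", file.path(...), call. = FALSE)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(msg) stop(msg, call. = FALSE)

check_that <- function(cond, msg) if (!isTRUE(cond)) stop_field(msg)

# linear-up / log-down trapezoidal AUC
auc_trapz <- function(time, conc) {
  stopifnot(length(time) == length(conc))
  if (length(time) < 2) return(0)
  dt <- diff(time)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  seg <- dt * (c1 + c2) / 2
  logdown <- which(c2 < c1 & c2 > 0 & c1 > 0)
  seg[logdown] <- dt[logdown] * (c1[logdown] - c2[logdown]) /
    log(c1[logdown] / c2[logdown])
  sum(seg)
}
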