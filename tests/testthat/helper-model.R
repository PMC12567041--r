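# shared fixtures: the calibrated model object is cached in the package
# environment, so repeated calls across test files are cheap
asc_model <- function() asciminib_model()
ref_subject <- function() mean_subject()

# tiny synthetic profile helpers for NCA oracles
flat_profile <- function(C, tau, dt = 0.5) {
  data.frame(time = seq(0, tau, by = dt), conc = C)
}
monoexp_profile <- function(C0, k, t_end, dt = 0.05) {
  tt <- seq(0, t_end, by = dt)
  data.frame(time = tt, conc = C0 * exp(-k * tt))
}
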