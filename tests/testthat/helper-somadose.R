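# Shared fixtures, built in code.

# Reference-like parameter sets with fast, well-conditioned dynamics.
quick_pk <- function(...) {
  args <- utils::modifyList(list(ka = 4, CL = 12 * log(2) / 2.5, V = 12,
                                 Vmax = 0, Km = 0.05, F = 0.7), list(...))
  do.call(pk_params, args)
}
quick_pd <- function(...) {
  args <- utils::modifyList(list(R0 = 120, kout = 0.7, Emax = 8.6,
                                 EC50 = 0.66, gamma = 1), list(...))
  do.call(pd_params, args)
}

# Calibrated parameter sets are expensive (about a minute); compute once
# per test run and share across files.
.cal_cache <- new.env(parent = emptyenv())

calibrated_soma <- function() {
  if (is.null(.cal_cache$soma)) {
    pop <- calibrate_mean_curves(reference_population())
    .cal_cache$soma <- calibrate_iiv(pop, n = 20000, seed = 20330)
  }
  .cal_cache$soma
}

calibrated_trop <- function() {
  if (is.null(.cal_cache$trop)) {
    .cal_cache$trop <- calibrate_somatropin(calibrated_soma())
  }
  .cal_cache$trop
}

# Small event-record dataset for estimation tests: n subjects on fixed
# weekly dosing with sparse PK/IGF-I sampling.
small_trial <- function(n = 12, seed = 301, pop = reference_population(),
                        noise = TRUE) {
  cov <- generate_demographics(demographics_spec(n = n), seed = seed)
  des <- default_trial_design(duration_weeks = 8, peak_weeks = c(1, 5),
                              trough_weeks = c(3, 7),
                              titration_weeks = c(2, 4))
  generate_trial(cov, pop, design = des, seed = seed + 1, noise = noise)
}
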