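# Shared fixtures, built in code. Kept tiny: larger simulations live in the
# tests that need them.

# One realized subject session with known behavioral parameters.
synth_behavior <- function(seed = 42, k = 0.02, b = 0.5) {
  cfg <- cohort_config(seed = seed)
  simulate_subject_behavior(cfg, 1, k = k, b = b)
}

# Input streams for the first `n_vol` volumes of run 1 of a session.
synth_inputs <- function(beh, n_vol = 323, tr = 2.5, dt = 0.1) {
  fit <- list(k = beh$k)
  rdsv <- rdsv_series(beh$trials, fit, beh$group)
  sel <- beh$trials$run == 1 & beh$trials$onset + 3.5 < n_vol * tr
  build_input_set(beh$trials[sel, , drop = FALSE], rdsv[sel], n_vol, tr, dt)
}

# A small planted cohort (reduced scale) plus its estimated feature table.
synth_cohort_features <- function(seed, n_subjects = 27L, effect_size = 0.25) {
  co <- simulate_cohort(cohort_config(seed = seed, n_subjects = n_subjects,
                                      runs_per_subject = 1L,
                                      effect_size = effect_size))
  list(cohort = co, features = extract_features(co))
}
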