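# Shared fixtures: noise-free profiles give deterministic trajectories that
# serve as the oracle for the simulator, the screens and the ROC checks.

zero_noise_profiles <- function() {
  lapply(default_profiles(), function(p) {
    p$relative_sd <- 0
    p
  })
}

zero_noise_cohort <- function(seed = 1, ...) {
  simulate_cohort(zero_noise_profiles(), seed = seed, ...)
}

noisy_profiles <- function(relative_sd) {
  lapply(default_profiles(), function(p) {
    p$relative_sd <- relative_sd
    p
  })
}

baseline_mid <- function(var) {
  p <- default_profiles()[[var]]
  (p$baseline_low + p$baseline_high) / 2
}

# Predictor frame + noise-free response from the published CBC-SCHEM
# equation, used by the coefficient-recovery checks.
schem_design <- function(seed, n = 92) {
  coh <- simulate_cohort(seed = seed)
  coh <- coh[seq_len(n), ]
  m <- published_model("CBC_SCHEM")
  coh$TIME <- coh$day
  list(cohort = coh, truth = c(m$alpha, m$beta),
       predictors = m$predictors,
       mean_response = apply_model(m, coh))
}
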