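# Shared fixtures: all synthetic, built in code.

# Reduced MCMC profile for property tests where only rough posterior
# location matters; the acceptance tests use mcmc_test_profile().
quick_spec <- function(transform = "identity", seed = 1L) {
  decay_model_spec(transform = transform, n_chains = 2, n_burnin = 200,
                   n_iter = 600, seed = seed)
}

# A small, fast simulation configuration.
small_sim <- function(seed = 1L, ...) {
  sim_config(n_sites = 8, n_days = 112, baseline_days = 28,
             colonies_per_site = 12, porites_topup = 5, seed = seed, ...)
}

# Noise-free metric parameter list: one shared slope/intercept, zero SDs.
noise_free_metrics <- function(ntu_intercept = 1.0, ntu_slope = -0.5) {
  list(
    ntu  = list(transform = "log10", intercept = ntu_intercept,
                slope = ntu_slope, sd_site = 0, sd_fortnight = 0,
                sd_resid = 0),
    dli  = list(transform = "sqrt", intercept = 1.5, slope = 1.0,
                sd_site = 0, sd_fortnight = 0, sd_resid = 0),
    depo = list(transform = "logit", intercept = 0, slope = -0.8,
                sd_site = 0, sd_fortnight = 0, sd_resid = 0)
  )
}
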