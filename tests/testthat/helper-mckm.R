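# shared fixtures, all built in code

# central clone of the default population
central_theta <- function() kinetic_parameters(mckm_population_defaults()$mean)

# noise-free run whose observations are exactly the simulated states
# (including the growth-rate state), the reference object for
# self-consistency checks
noise_free_run <- function(theta = central_theta(),
                           constants = model_constants(),
                           schedule = default_feed_schedule(constants = constants),
                           sample_times = default_sample_times()) {
  sim <- simulate_fedbatch(theta, default_initial_state(), constants,
                           schedule, sample_times, dense_n = 2)
  run <- culture_run(sim$times, sim$states, schedule,
                     list(campaign = "fixture", clone = "c1",
                          passage = "Ambr-1", replicate = 1L))
  attr(run, "theta_true") <- theta
  run
}

# small sensitivity matrix with controlled column geometry: columns at a
# prescribed angle for closed-form collinearity checks
angled_matrix <- function(phi, n = 8) {
  S <- matrix(0, n, 2, dimnames = list(NULL, c("a", "b")))
  S[1, ] <- c(1, cos(phi))
  S[2, 2] <- sin(phi)
  S
}
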