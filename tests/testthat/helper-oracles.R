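# exhaustive reference decoder: scores every position by explicitly
# multiplying per-axon normal densities (log taken at the end); shares no
# code with the package implementation
oracle_loglik <- function(mu, sd_, x) {
  vapply(seq_len(ncol(mu)), function(s) {
    acc <- 0
    for (i in seq_along(x)) {
      dens <- exp(-(x[i] - mu[i, s])^2 / (2 * sd_[i, s]^2)) /
        (sd_[i, s] * sqrt(2 * pi))
      acc <- acc + log(dens)
    }
    acc
  }, numeric(1))
}

# one small auditory session of gaussian-tuned boutons with centers drawn
# independently of any retinotopic position; returns what the best-azimuth
# analysis needs
quick_tuned_session <- function(seed, n_boutons = 20, n_reps = 4,
                                width = 20, amplitude = 0.5,
                                noise_sd = 0.05) {
  sc <- session_config(n_reps = n_reps, modalities = "auditory",
                       noise_sd = noise_sd, trial_gain_sd = 0.25,
                       seed = seed)
  log <- generate_stim_log(sc)
  pop <- generate_population(n_boutons, width_range = width,
                             amplitude_range = amplitude, seed = seed + 1)
  sim <- simulate_traces(log, pop, sc)
  tn <- segment_dff(sim$traces, log, pre_s = 1, post_s = 2)
  list(responses = trial_response(tn), log = log, geometry = sc$geometry,
       ground_truth = sim$ground_truth)
}
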