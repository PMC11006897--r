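# shared builders for synthetic test sessions

# noise-free deterministic config: no trial/bouton gain variability, no
# trace noise, short indicator and long gaps so trials do not interact
noiseless_config <- function(geometry = default_array(), n_reps = 2,
                             modalities = "auditory", seed = 1, ...) {
  session_config(geometry = geometry, n_reps = n_reps,
                 modalities = modalities, noise_sd = 0, trial_gain_sd = 0,
                 bouton_gain_sd = 0, indicator_tau = 0.3, isi = 5,
                 pre_time = 3, seed = seed, ...)
}

# single-axon population with explicit tuning
one_axon_pop <- function(kind = "gaussian", center = list(azimuth = 40,
                                                          elevation = 0),
                         width = 30, amplitude = 0.5, n_boutons = 1,
                         rho = 1, modality = "auditory") {
  ax <- list(axon_id = 1L, n_boutons = n_boutons, kind = kind,
             center = center, width = width, amplitude = amplitude,
             modality = modality, within_axon_corr = rho)
  gt <- data.frame(roi_id = seq_len(n_boutons), axon_id = 1L, kind = kind,
                   center_azimuth = center$azimuth,
                   center_elevation = center$elevation, width = width,
                   amplitude = amplitude, modality = modality,
                   responsive = kind != "nonresponsive")
  list(axons = list(ax), ground_truth = gt)
}

# quick session -> trial responses for a generated population
session_responses <- function(pop, config) {
  log <- generate_stim_log(config)
  sim <- simulate_traces(log, pop, config)
  tensor <- segment_dff(sim$traces, log, pre_s = 1, post_s = 2)
  list(log = log, sim = sim, tensor = tensor,
       responses = trial_response(tensor),
       labels = position_index(config$geometry, log$azimuth, log$elevation))
}

# benchmark conditions for axon-clustering recovery: distinct centers,
# strong shared trial-gain variability, within-axon correlation target 0.6
clustering_benchmark <- function(seed = 1, n_axons = 20, n_boutons = 3,
                                 rho = 0.6) {
  g <- default_array()
  sc <- session_config(n_reps = 20, modalities = "auditory",
                       noise_sd = 0.05, trial_gain_sd = 1,
                       seed = seed)
  set.seed(seed + 7)
  centers <- g$positions[sample.int(n_positions(g), n_axons), ]
  pop <- generate_population(n_axons, boutons_per_axon = n_boutons,
                             width_range = 12, amplitude_range = 0.5,
                             centers = centers, replace = FALSE,
                             within_axon_corr = rho, seed = seed + 1)
  c(session_responses(pop, sc), list(ground_truth = pop$ground_truth))
}
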