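test_that("SMI matches its closed form on canonical maps", {
  expect_equal(smi(c(1, 1, 1, 1)), 0)
  expect_equal(smi(rep(2.7, 39)), 0)
  for (n in c(2, 4, 13, 39)) {    # one-hot map: (n-1)/n exactly
    expect_equal(smi(c(1, rep(0, n - 1))), (n - 1) / n)
  }
  expect_equal(smi(c(2, 0)), 0.5)
  expect_error(smi(rep(0, 5)), "undefined")
})

test_that("SMI is scale invariant, bounded, and grows under concentration", {
  set.seed(81)
  for (i in 1:30) {
    r <- runif(10)
    expect_equal(smi(r), smi(17.3 * r), tolerance = 1e-12)
    expect_gte(smi(r), 0)
    expect_lte(smi(r), 1)
  }
  # mean-preserving concentration: move mass from one entry to another
  r <- c(4, 4, 2, 2)
  more <- c(6, 2, 2, 2)       # same mean, more concentrated
  expect_gt(smi(more), smi(r))
  expect_gt(smi(c(10, 0, 1, 1)), smi(c(7, 3, 1, 1)))
})

test_that("population SMI is the SMI of the averaged map", {
  maps <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0))
  expect_equal(population_smi(maps), smi(c(1, 0, 0, 0)))
  two <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(population_smi(two), smi(c(0.5, 0.5, 0, 0)))
  # spread tuning centers: the average map is flatter than the individuals
  set.seed(82)
  g <- default_array()
  d2 <- as.matrix(dist(g$positions))
  centers <- sample.int(39, 25, replace = TRUE)
  maps <- t(vapply(centers, function(ci) exp(-d2[ci, ]^2 / (2 * 25^2)),
                   numeric(39)))
  expect_lt(population_smi(maps), mean(apply(maps, 1, smi)))
  expect_error(population_smi(maps[0, , drop = FALSE]), "empty")
})

test_that("response maps average trials by position", {
  g <- array_geometry(c(0, 10), 0)
  log <- data.frame(azimuth = c(0, 10, 0, 10), elevation = 0)
  resp <- matrix(c(1, 3, 5, 7), 1)
  m <- response_map(resp, log, g)
  expect_equal(as.vector(m), c(3, 5))
  # permutation of trials within position leaves the map unchanged
  perm <- c(3, 2, 1, 4)
  expect_equal(response_map(resp[, perm, drop = FALSE], log[perm, ], g), m)
  expect_error(response_map(matrix(1, 1, 2),
                            data.frame(azimuth = c(0, 0), elevation = 0), g),
               "zero trials")
  # noise-free tuned bouton: map equals the kernel-attenuated tuning
  sc <- noiseless_config(n_reps = 2, seed = 83)
  ctr <- list(azimuth = 40, elevation = 0)
  log2 <- generate_stim_log(sc)
  sim <- simulate_traces(log2, one_axon_pop(center = ctr, width = 30), sc)
  tn <- segment_dff(sim$traces, log2, pre_s = 1, post_s = 2)
  m2 <- response_map(trial_response(tn), log2, sc$geometry)
  d <- angular_distance(sc$geometry$positions, ctr)
  expect_equal(as.vector(m2),
               0.5 * exp(-d^2 / (2 * 30^2)) * kernel_attenuation(sc),
               tolerance = 1e-6)
})

test_that("split-half reliability separates tuned from noise boutons", {
  g <- default_array()
  sc <- noiseless_config(n_reps = 4, seed = 84)
  log <- generate_stim_log(sc)
  sim <- simulate_traces(log, one_axon_pop(width = 25), sc)
  tn <- segment_dff(sim$traces, log, pre_s = 1, post_s = 2)
  resp <- trial_response(tn)
  rel <- split_half_reliability(resp, log, g, n_iter = 10, seed = 1)
  expect_equal(rel$mean_r[1], 1, tolerance = 1e-9)
  expect_true(rel$reliable[1])
  # pure noise
  set.seed(85)
  noise <- matrix(rnorm(20 * nrow(log), 0, 0.1), 20)
  reln <- split_half_reliability(noise, log, g, n_iter = 20, seed = 2)
  expect_lt(max(abs(reln$mean_r)), 0.25)
  expect_false(any(reln$reliable))
  # determinism of the split assignments
  expect_identical(split_half_reliability(noise, log, g, n_iter = 5,
                                          seed = 7)$r_iter,
                   split_half_reliability(noise, log, g, n_iter = 5,
                                          seed = 7)$r_iter)
})

test_that("session best azimuth is recovered with its reliability gate", {
  g <- default_array()
  sc <- session_config(n_reps = 5, modalities = "auditory", noise_sd = 0.02,
                       trial_gain_sd = 0.1, seed = 86)
  log <- generate_stim_log(sc)
  ctr <- list(azimuth = 40, elevation = 0)
  pop <- one_axon_pop(center = ctr, width = 20, n_boutons = 12, rho = 1)
  sim <- simulate_traces(log, pop, sc)
  tn <- segment_dff(sim$traces, log, pre_s = 1, post_s = 2)
  resp <- trial_response(tn)
  ba <- best_azimuth_session(resp, log, g, n_iter = 20, seed = 3)
  expect_true(ba$included)
  expect_equal(ba$mean_median, 40)
  expect_equal(ba$ci, c(40, 40))
  # 9 reliable boutons with min_reliable 10: session excluded
  ba9 <- best_azimuth_session(resp[1:9, ], log, g, n_iter = 10, seed = 4)
  expect_false(ba9$included)
  expect_true(is.na(ba9$mean_median))
})

test_that("best azimuth recovery is near-perfect at high SNR", {
  g <- default_array()
  sc <- session_config(n_reps = 20, modalities = "auditory",
                       noise_sd = 0.05, trial_gain_sd = 0.1, seed = 87)
  log <- generate_stim_log(sc)
  # narrow tuning: adjacent 10-deg columns must be distinguishable at all
  pop <- generate_population(60, width_range = 12,
                             amplitude_range = 0.5, seed = 88)
  sim <- simulate_traces(log, pop, sc)
  tn <- segment_dff(sim$traces, log, pre_s = 1, post_s = 2)
  resp <- trial_response(tn)
  rel <- split_half_reliability(resp, log, g, n_iter = 20, seed = 5)
  maps <- response_map(resp, log, g)
  best <- g$azimuths[max.col(vapply(g$azimuths, function(a)
    rowMeans(maps[, g$positions$azimuth == a, drop = FALSE]),
    numeric(nrow(maps))), ties.method = "first")]
  truth <- sim$ground_truth$center_azimuth
  expect_gt(mean(best[rel$reliable] == truth[rel$reliable]), 0.95)
})

test_that("distance tuning curves peak at zero and fall off", {
  g <- default_array()
  sc <- session_config(n_reps = 6, modalities = "auditory", noise_sd = 0.03,
                       trial_gain_sd = 0.1, seed = 89)
  log <- generate_stim_log(sc)
  pop <- generate_population(20, width_range = 25, amplitude_range = 0.4,
                             seed = 90)
  sim <- simulate_traces(log, pop, sc)
  tn <- segment_dff(sim$traces, log, pre_s = 1, post_s = 2)
  resp <- trial_response(tn)
  curve <- distance_tuning_curves(resp, log, g, n_iter = 20, seed = 6)
  expect_equal(curve$mean[curve$distance == 0], 1, tolerance = 0.02)
  far <- curve$mean[curve$distance > 80]
  expect_true(all(far < 0.6))
  # flat boutons: flat curve near 1
  popf <- generate_population(10, tuning_mixture = c(gaussian = 0,
                                                     flat_responsive = 1,
                                                     nonresponsive = 0),
                              amplitude_range = 0.4, seed = 91)
  simf <- simulate_traces(log, popf, sc)
  tnf <- segment_dff(simf$traces, log, pre_s = 1, post_s = 2)
  # flat maps have near-zero split-half r, so the gate is disabled here
  curvef <- distance_tuning_curves(trial_response(tnf), log, g,
                                   r_thresh = -1.1, n_iter = 10, seed = 7)
  expect_true(all(abs(curvef$mean - 1) < 0.1))
})

test_that("virtual-array ANOVA fractions reflect the modulated axis", {
  g <- default_array()
  sc <- session_config(n_reps = 4, modalities = "auditory", seed = 92)
  log <- generate_stim_log(sc)
  set.seed(93)
  n_roi <- 30
  # azimuth-only tuned responses, built directly at the response level
  az_resp <- t(vapply(seq_len(n_roi), function(i) {
    ctr <- sample(g$azimuths, 1)
    0.4 * exp(-(log$azimuth - ctr)^2 / (2 * 15^2)) +
      rnorm(nrow(log), 0, 0.05)
  }, numeric(nrow(log))))
  fr_az <- azimuth_elevation_fractions(az_resp, log, g)
  expect_gt(fr_az$fractions["azimuth"], 3 * fr_az$fractions["elevation"])
  # pure noise: each fraction near the 5% level
  noise <- matrix(rnorm(n_roi * nrow(log), 0, 0.1), n_roi)
  fr_n <- azimuth_elevation_fractions(noise, log, g)
  expect_true(all(fr_n$fractions < 0.12))
  # isotropic tuning: azimuth and elevation fractions comparable
  iso <- t(vapply(seq_len(n_roi), function(i) {
    ci <- sample.int(39, 1)
    d <- angular_distance(log, g$positions[ci, ])
    0.4 * exp(-d^2 / (2 * 15^2)) + rnorm(nrow(log), 0, 0.05)
  }, numeric(nrow(log))))
  fr_i <- azimuth_elevation_fractions(iso, log, g)
  expect_lt(abs(fr_i$fractions["azimuth"] - fr_i$fractions["elevation"]),
            0.3)
})

test_that("onset and offset classes follow the event timing", {
  fr <- 6
  onset <- seq(13, 400, by = 24)
  n <- max(onset) + 24
  log <- data.frame(trial = seq_along(onset),
                    onset_time_s = (onset - 1) / fr, onset_frame = onset,
                    modality = "auditory", azimuth = 0, elevation = 0,
                    intensity = 1)
  mk <- function(which_frames) {
    ev <- matrix(0, 1, n)
    for (o in onset) ev[1, o + which_frames] <- 0.5
    ev
  }
  ev <- rbind(mk(0:5), mk(6:11), matrix(0, 1, n))  # stim / post / silent
  f <- 1 + 0.2 * ev
  tr <- roi_traces(f, fr, events = ev)
  tn <- segment_dff(tr, log, pre_s = 1, post_s = 3)
  cls <- classify_onset_offset(tn)
  expect_equal(cls$class, c("onset", "offset", "none"))
  tr_no_ev <- roi_traces(f, fr)
  tn2 <- segment_dff(tr_no_ev, log, pre_s = 1, post_s = 3)
  expect_error(classify_onset_offset(tn2), "event")
})

test_that("frequency tuning distinguishes tuned, flat and weak responses", {
  set.seed(94)
  freqs <- rep(c(2, 4, 8, 16, 32), each = 12)
  base <- matrix(rnorm(3 * length(freqs), 0, 0.02), 3)
  resp <- rbind(
    ifelse(freqs == 8, 0.5, 0) + rnorm(length(freqs), 0, 0.02),   # tuned
    0.05 + rnorm(length(freqs), 0, 0.02),                         # weak
    0.4 + rnorm(length(freqs), 0, 0.02))                          # flat
  ft <- frequency_tuning(resp, base, freqs)
  expect_true(ft$per_roi$responsive[1])
  expect_true(ft$per_roi$tuned[1])
  expect_equal(ft$per_roi$best_freq[1], 8)
  expect_false(ft$per_roi$responsive[2])
  expect_true(ft$per_roi$responsive[3])
  expect_false(ft$per_roi$tuned[3])
  # curves normalized to the best frequency
  c1 <- ft$curves[ft$curves$best_freq == 8, ]
  expect_equal(max(c1$mean_norm), 1, tolerance = 1e-9)
  expect_error(frequency_tuning(resp, base, rep(8, length(freqs))),
               "frequencies")
})
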