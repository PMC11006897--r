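test_that("stimulus logs are block-randomized with exact position counts", {
  sc <- session_config(n_reps = 20, seed = 5)
  log <- generate_stim_log(sc)
  tab <- table(log$modality, paste(log$azimuth, log$elevation))
  expect_true(all(tab == 20))
  expect_equal(nrow(log), 39 * 20 * 2)
  # within every block of 78 stimuli each modality shows each position once
  blk <- rep(seq_len(20), each = 78)
  for (b in 1:3) {
    sub <- log[blk == b, ]
    expect_true(all(table(sub$modality,
                          paste(sub$azimuth, sub$elevation)) == 1))
  }
  expect_true(all(diff(log$onset_time_s) == sc$stim_duration + sc$isi))
  expect_identical(log, generate_stim_log(sc))   # determinism
  # degenerate design
  tiny <- session_config(geometry = array_geometry(0, 0), n_reps = 1,
                         modalities = "auditory", seed = 1)
  expect_equal(nrow(generate_stim_log(tiny)), 1)
})

test_that("population generation respects the tuning mixture", {
  pop <- generate_population(10, width_range = 30, seed = 2)
  expect_length(pop$axons, 10)
  expect_true(all(vapply(pop$axons, `[[`, "", "kind") == "gaussian"))
  expect_true(all(vapply(pop$axons, `[[`, 1, "width") == 30))
  mix <- c(gaussian = 0.5, flat_responsive = 0.3, nonresponsive = 0.2)
  big <- generate_population(1000, tuning_mixture = mix, seed = 3)
  counts <- table(factor(vapply(big$axons, `[[`, "", "kind"), names(mix)))
  for (k in names(mix)) {   # binomial 3-sigma band
    expect_lt(abs(counts[[k]] - 1000 * mix[[k]]),
              3 * sqrt(1000 * mix[[k]] * (1 - mix[[k]])))
  }
  expect_identical(generate_population(50, seed = 9),
                   generate_population(50, seed = 9))
  expect_error(generate_population(0), "empty")
})

test_that("simulated responses follow the programmed tuning", {
  sc <- noiseless_config(n_reps = 2, seed = 7)
  log <- generate_stim_log(sc)
  # nonresponsive axon: all-zero latent signal
  simn <- simulate_traces(log, one_axon_pop("nonresponsive", amplitude = 0),
                          sc)
  expect_true(all(abs(simn$signal) < 1e-12))
  # gaussian axon, noise-free: largest mean trial response at its center
  simg <- simulate_traces(log, one_axon_pop("gaussian",
                                            center = list(azimuth = 30,
                                                          elevation = 0),
                                            width = 25), sc)
  tn <- segment_dff(simg$traces, log, pre_s = 1, post_s = 2)
  m <- response_map(trial_response(tn), log, sc$geometry)
  best <- which.max(m[1, ])
  expect_equal(sc$geometry$positions$azimuth[best], 30)
  expect_equal(sc$geometry$positions$elevation[best], 0)
  # determinism
  sc2 <- session_config(n_reps = 1, modalities = "auditory", seed = 13)
  log2 <- generate_stim_log(sc2)
  pop <- generate_population(5, boutons_per_axon = 2, seed = 14)
  expect_identical(simulate_traces(log2, pop, sc2)$traces$f,
                   simulate_traces(log2, pop, sc2)$traces$f)
})

test_that("within-axon correlation calibration hits its target", {
  sc <- session_config(n_reps = 20, modalities = "auditory", noise_sd = 0.1,
                       trial_gain_sd = 0.5, seed = 21)
  log <- generate_stim_log(sc)   # 780 trials
  pop <- one_axon_pop("gaussian", width = 20, amplitude = 0.5,
                      n_boutons = 2, rho = 0.6)
  sim <- simulate_traces(log, pop, sc)
  tn <- segment_dff(sim$traces, log, pre_s = 1, post_s = 2)
  resp <- trial_response(tn)
  r <- cor(resp[1, ], resp[2, ])
  expect_gt(r, 0.45)
  expect_lt(r, 0.75)
})

test_that("fluorescence deconvolves back to the event trace", {
  sc <- noiseless_config(n_reps = 1, seed = 8)
  log <- generate_stim_log(sc)
  sim <- simulate_traces(log, one_axon_pop(), sc)
  f <- sim$traces$f[1, ] / sc$baseline_f - 1   # signal component
  d <- exp(-1 / (sc$frame_rate * sc$indicator_tau))
  dec <- (f - d * c(0, f[-length(f)])) / (1 - d)
  expect_lt(max(abs(dec - sim$traces$events[1, ])), 1e-6)
})

test_that("mean responses fall off monotonically with distance from center", {
  sc <- noiseless_config(n_reps = 1, seed = 9)
  log <- generate_stim_log(sc)
  ctr <- list(azimuth = 40, elevation = 0)
  sim <- simulate_traces(log, one_axon_pop(center = ctr, width = 30), sc)
  d <- angular_distance(log, ctr)
  fit <- lm(sim$signal[1, ] ~ d)
  expect_lt(coef(fit)[2], 0)
  # and exactly Gaussian in distance on the noise-free latent
  expect_equal(sim$signal[1, ], 0.5 * exp(-d^2 / (2 * 30^2)),
               tolerance = 1e-12)
})

test_that("V1 population RFs jitter around the population center", {
  sc <- session_config(n_reps = 2, modalities = "visual", noise_sd = 0.02,
                       seed = 10)
  v1 <- simulate_v1_population(list(azimuth = 50, elevation = 0),
                               rf_width = 20, center_jitter = 0,
                               n_neurons = 5, config = sc)
  tn <- segment_dff(v1$traces, v1$stim_log, pre_s = 1, post_s = 2)
  m <- colMeans(response_map(trial_response(tn), v1$stim_log, sc$geometry))
  best <- which.max(m)
  expect_equal(sc$geometry$positions$azimuth[best], 50)
  expect_equal(sc$geometry$positions$elevation[best], 0)
  v2 <- simulate_v1_population(list(azimuth = 50, elevation = 0),
                               center_jitter = 5, n_neurons = 50,
                               config = sc)
  expect_lt(abs(mean(v2$ground_truth$center_azimuth) - 50), 2)
  expect_identical(
    simulate_v1_population(list(azimuth = 50, elevation = 0),
                           config = sc)$traces$f,
    simulate_v1_population(list(azimuth = 50, elevation = 0),
                           config = sc)$traces$f)
})

test_that("audiovisual sessions have the stated design and gain structure", {
  sc <- session_config(n_reps = 7, noise_sd = 0.03, trial_gain_sd = 0.1,
                       seed = 12)
  av <- simulate_av_session(av_gain = 1.5, config = sc, n_neurons = 15,
                            center_jitter = 0)
  combos <- table(av$stim_log$condition, av$stim_log$offset, useNA = "ifany")
  expect_true(all(combos[combos > 0] == 7))
  expect_equal(sum(av$stim_log$condition == "V"), 7)
  expect_equal(sum(av$stim_log$condition == "A"), 35)
  # AV/V latent ratio is the programmed gain
  v_mean <- rowMeans(av$signal[, av$stim_log$condition == "V"])
  av_mean <- rowMeans(av$signal[, av$stim_log$condition == "AV"])
  expect_gt(mean(av_mean / v_mean), 1.4)
  expect_lt(mean(av_mean / v_mean), 1.6)
  # gain 1: AV and V indistinguishable
  av0 <- simulate_av_session(av_gain = 1, config = sc, n_neurons = 15,
                             center_jitter = 0)
  v0 <- rowMeans(av0$signal[, av0$stim_log$condition == "V"])
  a0 <- rowMeans(av0$signal[, av0$stim_log$condition == "AV"])
  expect_gt(t.test(a0, v0, paired = TRUE)$p.value, 0.05)
})
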