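# a minimal hand-built session: one ROI, constant baseline b with a plateau
# of height h*b during each 6-frame stimulus window
flat_plateau_traces <- function(b = 2, h = 1, n_trials = 4, fr = 6) {
  spacing <- 18             # 3 s at 6 Hz
  onset <- 13 + spacing * (seq_len(n_trials) - 1)
  n <- max(onset) + 24
  f <- matrix(b, 1, n)
  for (o in onset) f[1, o:(o + 5)] <- b * (1 + h)
  log <- data.frame(trial = seq_len(n_trials),
                    onset_time_s = (onset - 1) / fr, onset_frame = onset,
                    modality = "auditory", azimuth = 0, elevation = 0,
                    intensity = 1)
  list(traces = roi_traces(f, fr), log = log)
}

test_that("neuropil correction subtracts the scaled neuropil channel", {
  tr <- roi_traces(matrix(1, 1, 10), 6, fneu = matrix(1, 1, 10))
  expect_equal(neuropil_correct(tr, 0.7)$f[1, 1], 0.3)
  expect_equal(neuropil_correct(tr, 0)$f, tr$f)
  tr0 <- roi_traces(matrix(1, 1, 10), 6, fneu = matrix(0, 1, 10))
  expect_equal(neuropil_correct(tr0)$f[1, 1], 1)
  expect_error(neuropil_correct(roi_traces(matrix(1, 1, 10), 6)),
               "neuropil")
})

test_that("dF/F is zero for constant traces and one for a doubling", {
  s <- flat_plateau_traces(b = 3, h = 0)
  tn <- segment_dff(s$traces, s$log, pre_s = 1, post_s = 2)
  expect_true(all(abs(tn$dff) < 1e-12))
  expect_equal(dim(tn$dff)[2], nrow(s$log))
  s2 <- flat_plateau_traces(b = 3, h = 1)
  tn2 <- segment_dff(s2$traces, s2$log, pre_s = 1, post_s = 2)
  instim <- tn2$rel_time >= 0 & tn2$rel_time < 1
  expect_true(all(abs(tn2$dff[1, , instim] - 1) < 1e-12))
  # non-positive baseline is an error
  bad <- flat_plateau_traces(b = 0)
  expect_error(segment_dff(bad$traces, bad$log), "F0")
})

test_that("dF/F is invariant to multiplicative gain of F", {
  set.seed(31)
  s <- flat_plateau_traces(b = 2, h = 0.5)
  s$traces$f <- s$traces$f * (1 + 0.1 * sin(seq_len(ncol(s$traces$f)) / 50))
  tn1 <- segment_dff(s$traces, s$log)
  s$traces$f <- 7.3 * s$traces$f
  tn2 <- segment_dff(s$traces, s$log)
  expect_equal(tn1$dff, tn2$dff, tolerance = 1e-12)
})

test_that("trial responses are window means with the right frame count", {
  s <- flat_plateau_traces(b = 1, h = 0)
  tn <- segment_dff(s$traces, s$log)
  expect_true(all(trial_response(tn) == 0))
  s2 <- flat_plateau_traces(b = 1, h = 1)
  tn2 <- segment_dff(s2$traces, s2$log)
  expect_true(all(abs(trial_response(tn2, c(0, 1)) - 1) < 1e-12))
  nf <- sum(tn2$rel_time >= 0.2 & tn2$rel_time < 1.8)
  expect_true(nf %in% 9:10)
  expect_error(trial_response(tn2, c(0.2, 0.21)), "empty")
})

test_that("noise-free responses equal programmed amplitude times the
           closed-form kernel attenuation", {
  sc <- noiseless_config(n_reps = 1, seed = 41)
  log <- generate_stim_log(sc)
  amp <- 0.5
  sim <- simulate_traces(log, one_axon_pop(amplitude = amp, width = 30), sc)
  tn <- segment_dff(sim$traces, log, pre_s = 1, post_s = 2)
  resp <- trial_response(tn)
  # independent oracle: numerically convolve a unit boxcar with the
  # normalized exponential kernel and average the window frames
  fr <- sc$frame_rate
  d <- exp(-1 / (fr * sc$indicator_tau))
  kern <- (1 - d) * d^(0:199)
  box <- rep(c(1, 0), c(6, 194))
  conv <- stats::convolve(box, rev(kern), type = "open")[1:200]
  rel <- (seq_len(200) - 1) / fr
  alpha <- mean(conv[rel >= 0.2 & rel < 1.8])
  expect_equal(as.vector(resp), sim$signal[1, ] * alpha, tolerance = 1e-6)
  expect_equal(kernel_attenuation(sc), alpha, tolerance = 1e-9)
})

test_that("the Wilcoxon responsiveness gate controls false positives", {
  set.seed(51)
  g <- array_geometry(c(0, 10, 20, 30), 0)
  sc <- session_config(geometry = g, n_reps = 20, modalities = "auditory",
                       noise_sd = 0.1, seed = 52)
  log <- generate_stim_log(sc)
  pop <- generate_population(300, tuning_mixture = c(gaussian = 0,
                                                     flat_responsive = 0,
                                                     nonresponsive = 1),
                             geometry = g, seed = 53)
  sim <- simulate_traces(log, pop, sc)
  tn <- segment_dff(sim$traces, log, pre_s = 1, post_s = 2)
  # amplitude gate disabled to isolate the test's level
  sel <- select_responsive_boutons(tn, alpha = 0.01, amp_thresh = -Inf)
  expect_lte(mean(sel$responsive), 0.02)
  # with the amplitude gate, pure noise is essentially never admitted
  sel2 <- select_responsive_boutons(tn, alpha = 0.01, amp_thresh = 0.15)
  expect_lte(mean(sel2$responsive), 0.005)
})

test_that("amplitude and power gates behave as specified", {
  sc <- noiseless_config(n_reps = 10, seed = 61)
  sc$noise_sd <- 0.02
  log <- generate_stim_log(sc)
  # strong response but amplitude 0.10: excluded regardless of p-value
  sim <- simulate_traces(log, one_axon_pop("flat_responsive",
                                           amplitude = 0.10 /
                                             kernel_attenuation(sc)), sc)
  tn <- segment_dff(sim$traces, log, pre_s = 1, post_s = 2)
  sel <- select_responsive_boutons(tn, amp_thresh = 0.15)
  expect_false(any(sel$responsive))
  expect_true(all(sel$p_value < 0.01))
  # strongly tuned boutons at low noise: nearly all admitted
  sc2 <- session_config(n_reps = 10, modalities = "auditory",
                        noise_sd = 0.05, seed = 62)
  log2 <- generate_stim_log(sc2)
  pop2 <- generate_population(40, width_range = 30,
                              amplitude_range = c(0.5, 0.8), seed = 63)
  sim2 <- simulate_traces(log2, pop2, sc2)
  tn2 <- segment_dff(sim2$traces, log2, pre_s = 1, post_s = 2)
  sel2 <- select_responsive_boutons(tn2)
  expect_gt(mean(sel2$responsive), 0.95)
  # bootstrap variant agrees on the strong boutons
  selb <- select_responsive_boutons(tn2, method = "bootstrap", n_boot = 200)
  expect_gt(mean(selb$responsive), 0.95)
})

test_that("somatic inclusion applies the neuropil and response gates", {
  set.seed(71)
  fr <- 6
  n <- 400
  onset <- seq(13, n - 24, by = 18)
  log <- data.frame(trial = seq_along(onset),
                    onset_time_s = (onset - 1) / fr, onset_frame = onset,
                    modality = "visual", azimuth = 0, elevation = 0,
                    intensity = 1)
  resp_sig <- function(gain) {
    f <- matrix(1, 1, n)
    for (o in onset) f[1, o:(o + 5)] <- 1 + gain
    f
  }
  # three neurons: at-neuropil (excluded), 10% above + responsive
  # (included), above neuropil but all-noise (excluded by response gate)
  f <- rbind(resp_sig(0.3) + matrix(rnorm(n, 0, 0.01), 1, n),
             1.10 * resp_sig(0.3) + matrix(rnorm(n, 0, 0.01), 1, n),
             1.10 + matrix(rnorm(n, 0, 0.02), 1, n))
  fneu <- matrix(1, 3, n)
  tr <- roi_traces(f, fr, fneu = fneu)
  tn <- segment_dff(neuropil_correct(tr), log)
  sel <- select_somata(tr, tn)
  expect_equal(sel$included, c(FALSE, TRUE, FALSE))
  expect_false(sel$above_neuropil[1])
  expect_true(sel$above_neuropil[2])
})
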