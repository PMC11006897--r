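#' Session configuration for the synthetic generator
#'
#' Bundles the acquisition and stimulus parameters shared by all synthetic
#' sessions. Defaults emulate the study conditions: ~6 Hz volumetric scanning
#' of a slow indicator, 1 s stimuli separated by 2 s, 20 repetitions of each
#' position per modality in a block-randomized design.
#'
#' @param geometry an `array_geometry` (default [default_array()]).
#' @param n_reps repetitions per position per modality.
#' @param modalities character subset of `c("auditory", "visual")`.
#' @param frame_rate imaging frame rate, Hz.
#' @param stim_duration stimulus duration, s.
#' @param isi inter-stimulus interval (offset to next onset), s.
#' @param indicator_tau mono-exponential indicator decay constant, s.
#' @param noise_sd white-noise s.d. of the fluorescence trace, dF/F units.
#' @param baseline_f baseline fluorescence level (arbitrary units).
#' @param trial_gain_sd lognormal s.d. (log scale) of the shared per-trial
#'   response gain.
#' @param bouton_gain_sd lognormal s.d. (log scale) of the per-bouton static
#'   gain.
#' @param pre_time time before the first stimulus onset, s (must cover the
#'   baseline window).
#' @param neuropil_frac if non-`NULL`, a neuropil channel `Fneu` is emitted
#'   at this fraction of `baseline_f`.
#' @param seed integer seed fixing all randomness of the session.
#' @return a list of class `session_config`.
#' @export
session_config <- function(geometry = default_array(), n_reps = 20,
                           modalities = c("auditory", "visual"),
                           frame_rate = 6, stim_duration = 1, isi = 2,
                           indicator_tau = 1, noise_sd = 0.1,
                           baseline_f = 1, trial_gain_sd = 0.25,
                           bouton_gain_sd = 0.2, pre_time = 2,
                           neuropil_frac = NULL, seed = 1) {
  stopifnot(inherits(geometry, "array_geometry"), n_reps >= 1,
            frame_rate > 0, stim_duration > 0, isi >= 0,
            indicator_tau > 0, noise_sd >= 0, baseline_f > 0,
            all(modalities %in% c("auditory", "visual")))
  structure(list(geometry = geometry, n_reps = n_reps,
                 modalities = modalities, frame_rate = frame_rate,
                 stim_duration = stim_duration, isi = isi,
                 indicator_tau = indicator_tau, noise_sd = noise_sd,
                 baseline_f = baseline_f, trial_gain_sd = trial_gain_sd,
                 bouton_gain_sd = bouton_gain_sd, pre_time = pre_time,
                 neuropil_frac = neuropil_frac, seed = as.integer(seed)),
            class = "session_config")
}

# first frame whose start time (frame f starts at (f-1)/rate) is >= t
.onset_frame <- function(t, frame_rate) {
  as.integer(ceiling(t * frame_rate + 1 - 1e-9))
}

#' Generate a block-randomized stimulus log
#'
#' Within each of `n_reps` blocks every position of each modality appears
#' exactly once; the randomization sequences of the two modalities are
#' independent and their stimuli are interleaved (A, V, A, V, ...) within the
#' block. Onsets are spaced `stim_duration + isi` apart starting at
#' `pre_time`.
#'
#' @param config a `session_config`.
#' @return data.frame with columns `trial`, `onset_time_s`, `onset_frame`,
#'   `modality`, `azimuth`, `elevation`, `intensity`.
#' @export
generate_stim_log <- function(config) {
  set.seed(config$seed)
  pos <- config$geometry$positions
  np <- nrow(pos)
  per_block <- lapply(seq_len(config$n_reps), function(b) {
    orders <- lapply(config$modalities, function(m) {
      ord <- sample.int(np)
      data.frame(modality = m, azimuth = pos$azimuth[ord],
                 elevation = pos$elevation[ord])
    })
    if (length(orders) == 1) return(orders[[1]])
    # interleave the independently randomized modality sequences
    inter <- orders[[1]][rep(seq_len(np), each = length(orders)), ]
    for (j in seq_along(orders)[-1]) {
      inter[seq(j, nrow(inter), by = length(orders)), ] <- orders[[j]]
    }
    inter
  })
  log <- do.call(rbind, per_block)
  rownames(log) <- NULL
  n <- nrow(log)
  spacing <- config$stim_duration + config$isi
  log$onset_time_s <- config$pre_time + (seq_len(n) - 1) * spacing
  log$onset_frame <- .onset_frame(log$onset_time_s, config$frame_rate)
  log$trial <- seq_len(n)
  log$intensity <- 1
  log[, c("trial", "onset_time_s", "onset_frame", "modality",
          "azimuth", "elevation", "intensity")]
}

#' Generate a synthetic bouton/axon population
#'
#' Draws axons with known spatial tuning: a mixture of Gaussian-tuned,
#' flat-responsive (equal response at every position) and non-responsive
#' units. Each axon carries one or more boutons sharing its tuning, plus a
#' target within-axon trial-response correlation realized later by
#' [simulate_traces()].
#'
#' @param n_axons number of axons (>= 1).
#' @param boutons_per_axon integer scalar or vector (recycled) of boutons
#'   per axon.
#' @param tuning_mixture named numeric proportions over
#'   `c(gaussian, flat_responsive, nonresponsive)`; must sum to 1.
#' @param width_range range (degrees) from which Gaussian tuning s.d. widths
#'   are drawn uniformly; a scalar fixes the width.
#' @param amplitude_range range of peak response amplitudes (dF/F) drawn
#'   uniformly; a scalar fixes the amplitude.
#' @param centers data.frame of candidate tuning centers
#'   (`azimuth`, `elevation`); defaults to the geometry grid, sampled
#'   uniformly.
#' @param replace sample centers with replacement (default); with
#'   `replace = FALSE` every axon gets a distinct center.
#' @param within_axon_corr target Pearson correlation of trial responses
#'   between boutons of one axon, in \[0, 1\].
#' @param modality modality the units respond to.
#' @param geometry an `array_geometry` supplying default centers.
#' @param seed integer seed.
#' @return list with `axons` (list of axon spec lists) and `ground_truth`
#'   (one data.frame row per bouton ROI).
#' @export
generate_population <- function(n_axons, boutons_per_axon = 1,
                                tuning_mixture = c(gaussian = 1,
                                                   flat_responsive = 0,
                                                   nonresponsive = 0),
                                width_range = 30, amplitude_range = 0.5,
                                centers = NULL, replace = TRUE,
                                within_axon_corr = 0.6,
                                modality = "auditory",
                                geometry = default_array(), seed = 1) {
  if (n_axons < 1) stop("empty population request")
  stopifnot(abs(sum(tuning_mixture) - 1) < 1e-8,
            within_axon_corr >= 0, within_axon_corr <= 1)
  kinds <- c("gaussian", "flat_responsive", "nonresponsive")
  mix <- tuning_mixture[kinds]
  mix[is.na(mix)] <- 0
  set.seed(seed)
  if (is.null(centers)) centers <- geometry$positions
  nb <- rep_len(boutons_per_axon, n_axons)
  kind <- sample(kinds, n_axons, replace = TRUE, prob = mix)
  if (!replace && nrow(centers) < n_axons)
    stop("need >= n_axons candidate centers when replace = FALSE")
  ci <- sample.int(nrow(centers), n_axons, replace = replace)
  width <- runif(n_axons, min(width_range), max(width_range))
  amp <- runif(n_axons, min(amplitude_range), max(amplitude_range))
  amp[kind == "nonresponsive"] <- 0
  axons <- lapply(seq_len(n_axons), function(i) {
    list(axon_id = i, n_boutons = nb[i], kind = kind[i],
         center = list(azimuth = centers$azimuth[ci[i]],
                       elevation = centers$elevation[ci[i]]),
         width = width[i], amplitude = amp[i], modality = modality,
         within_axon_corr = within_axon_corr)
  })
  gt <- do.call(rbind, lapply(axons, function(a) {
    data.frame(roi_id = NA_integer_, axon_id = a$axon_id,
               kind = a$kind, center_azimuth = a$center$azimuth,
               center_elevation = a$center$elevation, width = a$width,
               amplitude = a$amplitude, modality = a$modality,
               responsive = a$kind != "nonresponsive",
               stringsAsFactors = FALSE)[rep(1, a$n_boutons), ]
  }))
  gt$roi_id <- seq_len(nrow(gt))
  rownames(gt) <- NULL
  list(axons = axons, ground_truth = gt)
}

#' Closed-form kernel attenuation of window-mean responses
#'
#' A unit boxcar over the stimulus frames, convolved with the normalized
#' mono-exponential indicator kernel, has a window-mean below 1 because the
#' indicator rises over the early frames. This attenuation factor maps the
#' generator's programmed trial amplitudes onto the trial responses the
#' analysis measures, and is computed exactly from the decay per frame
#' `d = exp(-1/(frame_rate * tau))`: the convolved response at the m-th
#' post-onset frame is `1 - d^m` within the boxcar and decays as
#' `(1 - d^S) d^(m-S)` after it.
#'
#' @param config a `session_config` (frame rate, stimulus duration, tau).
#' @param window response window, s relative to onset (default the bouton
#'   window 0.2-1.8 s).
#' @return scalar attenuation factor in (0, 1\].
#' @export
kernel_attenuation <- function(config, window = c(0.2, 1.8)) {
  fr <- config$frame_rate
  d <- exp(-1 / (fr * config$indicator_tau))
  S <- max(1L, as.integer(round(config$stim_duration * fr)))
  m1 <- as.integer(ceiling(window[1] * fr + 1 - 1e-9))
  m2 <- as.integer(ceiling(window[2] * fr - 1e-9))
  if (m2 < m1) stop("empty window at this frame rate")
  m <- m1:m2
  resp <- ifelse(m <= S, 1 - d^m, (1 - d^S) * d^(m - S))
  mean(resp)
}

# variance a window-mean trial response acquires from the white trace noise
# (response window of W frames plus the B-frame baseline entering via F0)
.response_noise_var <- function(config, window = c(0.2, 1.8),
                                baseline_s = 1) {
  fr <- config$frame_rate
  w_frames <- sum(seq(0, 60) / fr >= window[1] & seq(0, 60) / fr < window[2])
  b_frames <- max(1L, round(baseline_s * fr))
  config$noise_sd^2 * (1 / w_frames + 1 / b_frames)
}

# mean tuning response of an axon spec at given stimulus positions/modality
.tuning_response <- function(axon, log) {
  r <- numeric(nrow(log))
  own <- log$modality == axon$modality
  if (axon$kind == "gaussian") {
    d <- angular_distance(log[own, , drop = FALSE], axon$center)
    r[own] <- axon$amplitude * exp(-d^2 / (2 * axon$width^2))
  } else if (axon$kind == "flat_responsive") {
    r[own] <- axon$amplitude
  }
  r
}

# render per-trial signal amplitudes into fluorescence + event traces.
# events: boxcar of the signal over the stimulus frames; fluorescence:
# recursive exponential filter normalized to unit steady-state gain.
.render_traces <- function(signal, log, config) {
  fr <- config$frame_rate
  n_stim_frames <- max(1L, as.integer(round(config$stim_duration * fr)))
  n_frames <- max(log$onset_frame) + n_stim_frames +
    as.integer(ceiling((config$isi + 5 * config$indicator_tau) * fr))
  n_roi <- nrow(signal)
  events <- matrix(0, n_roi, n_frames)
  for (t in seq_len(nrow(log))) {
    fidx <- log$onset_frame[t] + seq_len(n_stim_frames) - 1L
    events[, fidx] <- events[, fidx] + signal[, t]
  }
  decay <- exp(-1 / (fr * config$indicator_tau))
  fluo <- t(apply(events, 1, function(e) {
    (1 - decay) * stats::filter(e, decay, method = "recursive")
  }))
  if (n_roi == 1) fluo <- matrix(fluo, 1, n_frames)
  noise <- matrix(stats::rnorm(n_roi * n_frames, 0, config$noise_sd),
                  n_roi, n_frames)
  f <- config$baseline_f * (1 + fluo + noise)
  fneu <- NULL
  if (!is.null(config$neuropil_frac)) {
    fneu <- config$baseline_f * config$neuropil_frac *
      (1 + matrix(stats::rnorm(n_roi * n_frames, 0, config$noise_sd / 2),
                  n_roi, n_frames))
  }
  list(f = f, events = events, fneu = fneu)
}

#' Container for fluorescence traces
#'
#' @param f ROI x frame fluorescence matrix.
#' @param frame_rate Hz.
#' @param fneu optional neuropil matrix, same shape as `f`.
#' @param events optional ROI x frame deconvolved-event matrix.
#' @param roi_ids ROI identifiers (default row index).
#' @return object of class `roi_traces`.
#' @export
roi_traces <- function(f, frame_rate, fneu = NULL, events = NULL,
                       roi_ids = seq_len(nrow(f))) {
  stopifnot(is.matrix(f), frame_rate > 0)
  if (!is.null(fneu)) stopifnot(identical(dim(fneu), dim(f)))
  if (!is.null(events)) stopifnot(identical(dim(events), dim(f)))
  structure(list(f = f, fneu = fneu, events = events,
                 frame_rate = frame_rate, roi_ids = roi_ids),
            class = "roi_traces")
}

#' @export
print.roi_traces <- function(x, ...) {
  cat(sprintf("roi_traces: %d ROIs x %d frames at %.3g Hz%s%s\n",
              nrow(x$f), ncol(x$f), x$frame_rate,
              if (is.null(x$fneu)) "" else ", with neuropil",
              if (is.null(x$events)) "" else ", with events"))
  invisible(x)
}

#' Simulate fluorescence traces for a bouton population
#'
#' Per trial, each axon draws a latent response equal to its tuning amplitude
#' at the stimulus position times a shared lognormal trial gain. Each bouton
#' observes the shared latent scaled by its static gain plus independent
#' Gaussian noise whose variance is set in closed form so that the expected
#' within-axon bouton-bouton Pearson correlation over the session equals the
#' axon's `within_axon_corr` target. Trial signals are placed as boxcars
#' over the stimulus window, convolved with a normalized mono-exponential
#' indicator kernel `exp(-t/tau)`, sampled at the frame rate, and white noise
#' is added; the pre-kernel boxcar trace is emitted as the deconvolved-event
#' channel.
#'
#' @param stim_log data.frame from [generate_stim_log()].
#' @param population list from [generate_population()].
#' @param config a `session_config`.
#' @return list with `traces` (a `roi_traces`), `ground_truth` (per-ROI
#'   data.frame), and `signal` (bouton x trial latent response matrix,
#'   dF/F units, before kernel and trace noise).
#' @export
simulate_traces <- function(stim_log, population, config) {
  geom <- config$geometry
  on_grid <- paste(stim_log$azimuth, stim_log$elevation) %in%
    paste(geom$positions$azimuth, geom$positions$elevation)
  if (!all(on_grid)) stop("stimulus positions outside the geometry")
  set.seed(config$seed + 1L)
  n_tr <- nrow(stim_log)
  # calibration constants: the correlation target refers to trial responses
  # as the standard analysis measures them, so the kernel attenuation and
  # the trace-noise contribution to window means enter the mixing weight
  alpha <- kernel_attenuation(config)
  n0 <- .response_noise_var(config)
  rows <- list()
  for (a in population$axons) {
    mu <- .tuning_response(a, stim_log)
    gain <- stats::rlnorm(n_tr, -config$trial_gain_sd^2 / 2,
                          config$trial_gain_sd)
    latent <- mu * gain
    v <- stats::var(latent)
    rho <- a$within_axon_corr
    for (b in seq_len(a$n_boutons)) {
      bg <- stats::rlnorm(1, 0, config$bouton_gain_sd)
      if (rho <= 0 && v > 0) {
        # independent latents: each bouton redraws its own trial gains
        g2 <- stats::rlnorm(n_tr, -config$trial_gain_sd^2 / 2,
                            config$trial_gain_sd)
        rows[[length(rows) + 1L]] <- bg * mu * g2
      } else {
        # corr(resp_j, resp_k) = a^2 v / (a^2 (v + s^2) + n0) = rho
        eps_var <- if (v > 0 && rho < 1)
          max(v * (1 - rho) / rho - n0 / alpha^2, 0) else 0
        rows[[length(rows) + 1L]] <-
          bg * (latent + stats::rnorm(n_tr, 0, sqrt(eps_var)))
      }
    }
  }
  signal <- do.call(rbind, rows)
  rend <- .render_traces(signal, stim_log, config)
  gt <- population$ground_truth
  list(traces = roi_traces(rend$f, config$frame_rate, fneu = rend$fneu,
                           events = rend$events, roi_ids = gt$roi_id),
       ground_truth = gt, signal = signal)
}

#' Simulate a V1 somatic population with jittered 2D Gaussian visual RFs
#'
#' Neighboring V1 somata share retinotopy: each neuron's RF center is the
#' population center plus independent Gaussian jitter on both axes. The
#' trace model is identical to [simulate_traces()]; a neuropil channel is
#' emitted so the somatic inclusion filters can be applied.
#'
#' @param rf_center list/row with `azimuth`, `elevation` (degrees).
#' @param rf_width RF Gaussian s.d., degrees.
#' @param center_jitter s.d. of per-neuron center jitter, degrees.
#' @param n_neurons number of somata.
#' @param config a `session_config` (its `modalities` should include
#'   "visual"); if `neuropil_frac` is `NULL` it is set to 0.7.
#' @param amplitude peak visual response, dF/F.
#' @return list with `traces`, `ground_truth`, `signal`, `stim_log`.
#' @export
simulate_v1_population <- function(rf_center, rf_width = 15,
                                   center_jitter = 3, n_neurons = 30,
                                   config = session_config(), amplitude = 0.4) {
  if (is.null(config$neuropil_frac)) config$neuropil_frac <- 0.7
  stim_log <- generate_stim_log(config)
  set.seed(config$seed + 2L)
  axons <- lapply(seq_len(n_neurons), function(i) {
    list(axon_id = i, n_boutons = 1L, kind = "gaussian",
         center = list(azimuth = rf_center$azimuth +
                         stats::rnorm(1, 0, center_jitter),
                       elevation = rf_center$elevation +
                         stats::rnorm(1, 0, center_jitter)),
         width = rf_width, amplitude = amplitude, modality = "visual",
         within_axon_corr = 1)
  })
  gt <- do.call(rbind, lapply(axons, function(a) {
    data.frame(roi_id = a$axon_id, axon_id = a$axon_id, kind = a$kind,
               center_azimuth = a$center$azimuth,
               center_elevation = a$center$elevation,
               width = a$width, amplitude = a$amplitude,
               modality = a$modality, responsive = TRUE)
  }))
  sim <- simulate_traces(stim_log, list(axons = axons, ground_truth = gt),
                         config)
  sim$stim_log <- stim_log
  sim
}

#' Simulate an audiovisual V1 session
#'
#' Emulates the audiovisual protocol: a fixed target LED at the population
#' RF center, speakers offset from it in azimuth by
#' `{-40, -20, 0, +20, +40}` degrees, and trials of three conditions -
#' visual (V), auditory (A), audiovisual (AV) - each repeated `n_reps`
#' times per stimulus combination. By construction the visual response is
#' the neuron's RF Gaussian at the LED, the auditory response is a small
#' offset-independent baseline response, and the AV response is the visual
#' response scaled by `av_gain`, independent of the speaker offset.
#'
#' @param rf_center list with `azimuth`, `elevation`; the target LED sits
#'   here.
#' @param speaker_offsets azimuthal speaker offsets relative to the LED,
#'   degrees.
#' @param av_gain multiplicative AV/V response factor.
#' @param config a `session_config`; `n_reps` is the per-combination
#'   repetition count (7 in the emulated design).
#' @param n_neurons number of somata.
#' @param rf_width,center_jitter RF shape as in [simulate_v1_population()].
#' @param amplitude peak visual response, dF/F.
#' @param a_amplitude offset-independent auditory response, dF/F.
#' @param mouse label recorded in the ground truth (sessions from different
#'   animals are simulated with different seeds and labels).
#' @return list with `traces`, `stim_log` (columns `condition`, `offset`),
#'   `ground_truth`, `signal`.
#' @export
simulate_av_session <- function(rf_center = list(azimuth = 40, elevation = 0),
                                speaker_offsets = c(-40, -20, 0, 20, 40),
                                av_gain = 1.5,
                                config = session_config(n_reps = 7),
                                n_neurons = 20, rf_width = 15,
                                center_jitter = 3, amplitude = 0.4,
                                a_amplitude = 0.05, mouse = "m1") {
  set.seed(config$seed)
  cond <- rbind(
    data.frame(condition = "V", offset = NA_real_),
    data.frame(condition = "A", offset = speaker_offsets),
    data.frame(condition = "AV", offset = speaker_offsets))
  trials <- cond[rep(seq_len(nrow(cond)), config$n_reps), ]
  trials <- trials[sample.int(nrow(trials)), ]
  n_tr <- nrow(trials)
  spacing <- config$stim_duration + config$isi
  trials$onset_time_s <- config$pre_time + (seq_len(n_tr) - 1) * spacing
  trials$onset_frame <- .onset_frame(trials$onset_time_s, config$frame_rate)
  trials$trial <- seq_len(n_tr)
  trials$modality <- c(V = "visual", A = "auditory", AV = "audiovisual")[
    trials$condition]
  trials$azimuth <- ifelse(is.na(trials$offset), rf_center$azimuth,
                           rf_center$azimuth + trials$offset)
  trials$elevation <- rf_center$elevation
  trials$intensity <- 1
  rownames(trials) <- NULL

  centers_az <- rf_center$azimuth + stats::rnorm(n_neurons, 0, center_jitter)
  centers_el <- rf_center$elevation + stats::rnorm(n_neurons, 0, center_jitter)
  d <- sqrt((centers_az - rf_center$azimuth)^2 +
              (centers_el - rf_center$elevation)^2)
  v_amp <- amplitude * exp(-d^2 / (2 * rf_width^2))
  base <- matrix(0, n_neurons, n_tr)
  base[, trials$condition == "V"] <- v_amp
  base[, trials$condition == "A"] <- a_amplitude
  base[, trials$condition == "AV"] <- v_amp * av_gain
  gain <- matrix(stats::rlnorm(n_neurons * n_tr,
                               -config$trial_gain_sd^2 / 2,
                               config$trial_gain_sd), n_neurons, n_tr)
  signal <- base * gain
  rend <- .render_traces(signal, trials, config)
  if (is.null(config$neuropil_frac)) {
    rend$fneu <- config$baseline_f * 0.7 *
      matrix(1, n_neurons, ncol(rend$f))
  }
  gt <- data.frame(roi_id = seq_len(n_neurons), axon_id = seq_len(n_neurons),
                   kind = "gaussian", center_azimuth = centers_az,
                   center_elevation = centers_el, width = rf_width,
                   amplitude = v_amp, modality = "visual",
                   responsive = TRUE, mouse = mouse)
  list(traces = roi_traces(rend$f, config$frame_rate, fneu = rend$fneu,
                           events = rend$events),
       stim_log = trials, ground_truth = gt, signal = signal)
}
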