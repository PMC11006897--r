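#' Default end-to-end run configuration
#'
#' Collects every stage parameter of the axonal pipeline with its standard
#' value: responsiveness level 0.01 and amplitude gate 0.15 dF/F, split-half
#' reliability threshold 0.3 with 100 iterations, clustering threshold 0.3,
#' 5-fold cross-validation gated at >10 axons, 100 shuffles, neuropil
#' coefficient 0.7. All stage randomness derives from one master seed
#' (stage i uses `seed + 100 * i`), so stages are independently rerunnable.
#'
#' @param seed master seed.
#' @param n_axons,boutons_per_axon,tuning_mixture,width_range,amplitude_range,within_axon_corr
#'   synthetic population parameters (see [generate_population()]).
#' @param n_reps repetitions per position per modality.
#' @param noise_sd trace white-noise s.d., dF/F.
#' @param n_shuffles decoder shuffle count.
#' @param ... overrides for any `session_config` field.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, n_axons = 40, boutons_per_axon = 3,
                               tuning_mixture = c(gaussian = 0.6,
                                                  flat_responsive = 0.25,
                                                  nonresponsive = 0.15),
                               width_range = c(15, 60),
                               amplitude_range = c(0.3, 0.8),
                               within_axon_corr = 0.6, n_reps = 20,
                               noise_sd = 0.1, n_shuffles = 100, ...) {
  structure(list(seed = as.integer(seed), n_axons = n_axons,
                 boutons_per_axon = boutons_per_axon,
                 tuning_mixture = tuning_mixture,
                 width_range = width_range,
                 amplitude_range = amplitude_range,
                 within_axon_corr = within_axon_corr, n_reps = n_reps,
                 noise_sd = noise_sd, n_shuffles = n_shuffles,
                 alpha_responsive = 0.01, amp_thresh = 0.15,
                 r_thresh_reliability = 0.3, r_thresh_cluster = 0.3,
                 min_axons = 10, min_reliable = 10, k_folds = 5,
                 n_iter = 100, neuropil_coefficient = 0.7,
                 session = list(...)),
            class = "run_config")
}

#' Run the full axonal analysis pipeline on a synthetic session
#'
#' Simulates a session, segments and filters it, computes the spatial
#' tuning statistics, clusters boutons into axons, and runs the
#' cross-validated decoder with its shuffle null. Deterministic given the
#' config's master seed.
#'
#' @param config a `run_config` from [default_run_config()].
#' @return list with the intermediate products of every stage (`config`,
#'   `stim_log`, `ground_truth`, `tensor`, `responsive`, `tuning`,
#'   `assignment`, `decode`, `shuffle_errors`, `chance`).
#' @export
run_axonal_pipeline <- function(config = default_run_config()) {
  sc <- do.call(session_config,
                c(list(n_reps = config$n_reps, noise_sd = config$noise_sd,
                       modalities = "auditory",
                       seed = config$seed + 100L),
                  config$session))
  geom <- sc$geometry
  stim_log <- generate_stim_log(sc)
  pop <- generate_population(
    n_axons = config$n_axons, boutons_per_axon = config$boutons_per_axon,
    tuning_mixture = config$tuning_mixture,
    width_range = config$width_range,
    amplitude_range = config$amplitude_range,
    within_axon_corr = config$within_axon_corr, geometry = geom,
    seed = config$seed + 200L)
  sim <- simulate_traces(stim_log, pop, sc)
  tensor <- segment_dff(sim$traces, stim_log, pre_s = 1, post_s = 2)
  responses <- trial_response(tensor)
  responsive <- select_responsive_boutons(
    tensor, modality = "auditory", alpha = config$alpha_responsive,
    amp_thresh = config$amp_thresh)
  keep <- which(responsive$responsive)
  tuning <- NULL
  if (length(keep)) {
    maps <- response_map(responses[keep, , drop = FALSE], stim_log, geom)
    rel <- split_half_reliability(responses[keep, , drop = FALSE], stim_log,
                                  geom, r_thresh = config$r_thresh_reliability,
                                  n_iter = config$n_iter,
                                  seed = config$seed + 300L)
    tuning <- data.frame(roi_id = responsive$roi_id[keep],
                         smi = apply(maps, 1, smi),
                         split_half_r = rel$mean_r,
                         reliable = rel$reliable,
                         best_azimuth = .best_azimuth(maps, geom))
    tuning$population_smi <- population_smi(maps)
  }
  dff_flat <- matrix(tensor$dff, nrow = dim(tensor$dff)[1])
  assignment <- cluster_axons(dff_flat, r_thresh = config$r_thresh_cluster,
                              seed = config$seed + 400L)
  axon_resp <- cluster_activity(assignment, responses)
  labels <- position_index(geom, stim_log$azimuth, stim_log$elevation)
  decode <- crossval_decode(axon_resp, labels, geom, k = config$k_folds,
                            seed = config$seed + 500L,
                            min_axons = config$min_axons)
  shuffle <- if (!isTRUE(decode$skipped)) {
    shuffle_null(axon_resp, labels, geom, k = config$k_folds,
                 n_shuffles = config$n_shuffles,
                 seed = config$seed + 600L, min_axons = config$min_axons)
  } else NULL
  list(config = config, stim_log = stim_log,
       ground_truth = sim$ground_truth, tensor = tensor,
       responses = responses, responsive = responsive, tuning = tuning,
       assignment = assignment, decode = decode,
       shuffle_errors = shuffle, chance = chance_error(geom))
}

#' Summarize a pipeline run
#'
#' @param run output of [run_axonal_pipeline()].
#' @return one-row data.frame with the run's headline quantities: fraction
#'   of responsive boutons, mean and population SMI, axon count, observed
#'   decoding error, shuffle mean, and chance error.
#' @export
report_run <- function(run) {
  data.frame(
    n_rois = nrow(run$responsive),
    frac_responsive = mean(run$responsive$responsive),
    mean_smi = if (is.null(run$tuning)) NA_real_ else mean(run$tuning$smi),
    population_smi = if (is.null(run$tuning)) NA_real_ else
      run$tuning$population_smi[1],
    n_axons = run$assignment$n_clusters,
    decode_error = if (isTRUE(run$decode$skipped)) NA_real_ else
      run$decode$mean_error,
    shuffle_mean = if (is.null(run$shuffle_errors)) NA_real_ else
      mean(run$shuffle_errors, na.rm = TRUE),
    chance_error = run$chance)
}

#' Write a pipeline run to disk
#'
#' Writes the stimulus log, ground truth, per-ROI tables and decode trials
#' as CSV, the summary and configuration as JSON, and a manifest recording
#' the config hash and seed, into `dir`.
#'
#' @param run output of [run_axonal_pipeline()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$stim_log, file.path(dir, "stim_log.csv"),
                   row.names = FALSE)
  utils::write.csv(run$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(run$responsive, file.path(dir, "responsive.csv"),
                   row.names = FALSE)
  if (!is.null(run$tuning))
    utils::write.csv(run$tuning, file.path(dir, "tuning.csv"),
                     row.names = FALSE)
  utils::write.csv(
    data.frame(roi_id = seq_along(run$assignment$cluster),
               cluster_id = run$assignment$cluster,
               is_representative = seq_along(run$assignment$cluster) %in%
                 run$assignment$representative),
    file.path(dir, "clusters.csv"), row.names = FALSE)
  if (!isTRUE(run$decode$skipped))
    utils::write.csv(run$decode$trials, file.path(dir, "decode_trials.csv"),
                     row.names = FALSE)
  cfg <- unclass(run$config)
  if (!is.null(cfg$session$geometry)) {
    g <- cfg$session$geometry
    cfg$session$geometry <- list(azimuths = g$azimuths,
                                 elevations = g$elevations)
  }
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  writeLines(cfg_json, file.path(dir, "config.json"))
  jsonlite::write_json(report_run(run), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- list(seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(
                     file.path(dir, "config.json"))),
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   files = list.files(dir))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
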