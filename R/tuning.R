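#' Per-ROI response maps
#'
#' Averages scalar trial responses by stimulus position, yielding one mean
#' response per position per ROI (the response map the spatial modulation
#' index is computed on).
#'
#' @param responses ROI x trial matrix (e.g. from [trial_response()]).
#' @param log stimulus log rows matching the columns of `responses`.
#' @param geometry an `array_geometry`; map columns follow
#'   `geometry$positions` order.
#' @return ROI x position matrix with the geometry attached as attribute
#'   `"geometry"`.
#' @export
response_map <- function(responses, log, geometry) {
  idx <- position_index(geometry, log$azimuth, log$elevation)
  np <- n_positions(geometry)
  cnt <- tabulate(idx, np)
  if (any(cnt == 0)) stop("position(s) with zero trials")
  w <- matrix(0, ncol(responses), np)
  w[cbind(seq_along(idx), idx)] <- 1
  w <- sweep(w, 2, cnt, "/")
  m <- responses %*% w
  attr(m, "geometry") <- geometry
  m
}

#' Spatial modulation index (SMI)
#'
#' The fraction of a response map's energy not explained by its spatial
#' mean: `sum_i (r_i - R)^2 / sum_i r_i^2`, where `r_i` is the mean
#' response at position i and `R` the grand mean. 0 for a spatially uniform
#' map; `(n-1)/n` for a map confined to a single position.
#'
#' @param r numeric vector of per-position mean responses (one ROI's map).
#' @param rectify if `TRUE`, negative map entries are set to zero before
#'   evaluation (off by default; noise-driven negative responses enter
#'   as-is).
#' @return SMI in \[0, 1\] for nonnegative maps.
#' @export
smi <- function(r, rectify = FALSE) {
  r <- as.numeric(r)
  if (rectify) r <- pmax(r, 0)
  denom <- sum(r^2)
  if (denom == 0) stop("all-zero response map: SMI undefined")
  sum((r - mean(r))^2) / denom
}

#' Population SMI
#'
#' SMI of the position-wise mean map across ROIs (the population map of the
#' averaged responsive boutons).
#'
#' @param maps ROI x position matrix of response maps.
#' @param rectify passed to [smi()].
#' @return scalar SMI of the averaged map.
#' @export
population_smi <- function(maps, rectify = FALSE) {
  if (is.null(dim(maps)) || nrow(maps) == 0) stop("empty map set")
  smi(colMeans(maps), rectify = rectify)
}

# rowwise Pearson correlation of two matrices
.row_cor <- function(a, b) {
  ac <- a - rowMeans(a); bc <- b - rowMeans(b)
  num <- rowSums(ac * bc)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

# one random split of trials into two halves within each position; returns
# ROI x position mean maps of each half
.split_half_maps <- function(responses, idx, np) {
  g <- integer(length(idx))
  for (p in seq_len(np)) {
    tr <- which(idx == p)
    tr <- tr[sample.int(length(tr))]
    h <- length(tr) %/% 2
    g[tr[seq_len(h)]] <- 1L
    g[tr[-seq_len(h)]] <- 2L
  }
  mk <- function(h) {
    w <- matrix(0, length(idx), np)
    sel <- g == h
    w[cbind(which(sel), idx[sel])] <- 1
    w <- sweep(w, 2, pmax(colSums(w), 1), "/")
    responses %*% w
  }
  list(m1 = mk(1L), m2 = mk(2L), split = g)
}

#' Split-half tuning reliability
#'
#' Trials of each position are randomly split in half; the Pearson
#' correlation between the two half response maps measures tuning
#' reliability. Repeated `n_iter` times; a bouton is reliable when its mean
#' split-half correlation exceeds `r_thresh` (0.3 in the emulated analysis;
#' within resampling procedures the criterion is re-applied per iteration).
#'
#' @param responses ROI x trial matrix.
#' @param log matching stimulus log rows.
#' @param geometry an `array_geometry`.
#' @param r_thresh reliability threshold on the correlation.
#' @param n_iter number of random splits.
#' @param seed integer seed.
#' @return list with `mean_r` (per ROI), `reliable` (logical per ROI), and
#'   `r_iter` (ROI x iteration matrix of split-half correlations).
#' @export
split_half_reliability <- function(responses, log, geometry, r_thresh = 0.3,
                                   n_iter = 100, seed = 1) {
  idx <- position_index(geometry, log$azimuth, log$elevation)
  np <- n_positions(geometry)
  if (min(tabulate(idx, np)) < 2) stop("position with < 2 trials")
  set.seed(seed)
  r_iter <- vapply(seq_len(n_iter), function(k) {
    sh <- .split_half_maps(responses, idx, np)
    .row_cor(sh$m1, sh$m2)
  }, numeric(nrow(responses)))
  r_iter <- matrix(r_iter, nrow = nrow(responses))
  mean_r <- rowMeans(r_iter, na.rm = TRUE)
  list(mean_r = mean_r, reliable = !is.na(mean_r) & mean_r > r_thresh,
       r_iter = r_iter)
}

# per-ROI best azimuth: responses averaged across all trials, marginalized
# over elevation by averaging the position map within each azimuth column
.best_azimuth <- function(maps, geometry) {
  az <- geometry$positions$azimuth
  az_lev <- geometry$azimuths
  marg <- vapply(az_lev, function(a) rowMeans(maps[, az == a, drop = FALSE]),
                 numeric(nrow(maps)))
  marg <- matrix(marg, nrow = nrow(maps))
  az_lev[max.col(marg, ties.method = "first")]
}

#' Session best azimuth with resampled confidence interval
#'
#' The per-bouton best azimuth is the azimuth column with the largest mean
#' response (elevations averaged), estimated from all trials. Per resampling
#' iteration, boutons are re-qualified as reliable from a fresh random
#' split-half (correlation > `r_thresh`) and the session statistic is the
#' median best azimuth across the reliable boutons. The mean and 95%
#' interval over `n_iter` iterations are reported. Sessions are excluded
#' when fewer than `min_reliable` boutons qualify (in the median iteration).
#'
#' @inheritParams split_half_reliability
#' @param min_reliable minimum reliable-bouton count for session inclusion.
#' @return list with `included`, `mean_median` (mean of per-iteration median
#'   best azimuths), `ci` (2.5/97.5% quantiles), `n_reliable_median`, and
#'   `per_roi` (data.frame of best azimuth and mean split-half r).
#' @export
best_azimuth_session <- function(responses, log, geometry, r_thresh = 0.3,
                                 min_reliable = 10, n_iter = 100, seed = 1) {
  idx <- position_index(geometry, log$azimuth, log$elevation)
  np <- n_positions(geometry)
  maps <- response_map(responses, log, geometry)
  best_az <- .best_azimuth(maps, geometry)
  set.seed(seed)
  meds <- numeric(n_iter); n_rel <- integer(n_iter)
  for (k in seq_len(n_iter)) {
    sh <- .split_half_maps(responses, idx, np)
    r <- .row_cor(sh$m1, sh$m2)
    rel <- !is.na(r) & r > r_thresh
    n_rel[k] <- sum(rel)
    meds[k] <- if (sum(rel) >= min_reliable)
      stats::median(best_az[rel]) else NA_real_
  }
  included <- stats::median(n_rel) >= min_reliable
  list(included = included,
       mean_median = if (included) mean(meds, na.rm = TRUE) else NA_real_,
       ci = if (included)
         stats::quantile(meds, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
       else c(NA_real_, NA_real_),
       n_reliable_median = stats::median(n_rel),
       per_roi = data.frame(best_azimuth = best_az))
}

#' Distance tuning curves
#'
#' Per iteration, trials are split in half; each reliable bouton's preferred
#' position is taken from the first half and its second-half map is
#' normalized to the second-half response at that preferred position.
#' Normalized responses are pooled by distance from the preferred position
#' (degrees, rounded) across boutons, and the mean and 95% interval over
#' iterations are returned.
#'
#' @inheritParams split_half_reliability
#' @return data.frame with `distance`, `mean`, `lo`, `hi` (95% interval
#'   across iterations), `n_iter_obs`.
#' @export
distance_tuning_curves <- function(responses, log, geometry, r_thresh = 0.3,
                                   n_iter = 100, seed = 1) {
  idx <- position_index(geometry, log$azimuth, log$elevation)
  np <- n_positions(geometry)
  pos <- geometry$positions
  dmat <- round(sqrt(outer(pos$azimuth, pos$azimuth, "-")^2 +
                       outer(pos$elevation, pos$elevation, "-")^2))
  set.seed(seed)
  acc <- list()
  for (k in seq_len(n_iter)) {
    sh <- .split_half_maps(responses, idx, np)
    r <- .row_cor(sh$m1, sh$m2)
    pref <- max.col(sh$m1, ties.method = "first")
    peak <- sh$m2[cbind(seq_len(nrow(responses)), pref)]
    ok <- !is.na(r) & r > r_thresh & peak > 0
    if (!any(ok)) next
    d <- as.vector(t(dmat[pref[ok], , drop = FALSE]))
    v <- as.vector(t(sh$m2[ok, , drop = FALSE] / peak[ok]))
    acc[[length(acc) + 1L]] <-
      vapply(split(v, d), mean, numeric(1))
  }
  if (!length(acc)) stop("no reliable boutons in any iteration")
  dists <- sort(unique(as.numeric(unlist(lapply(acc, names)))))
  curve <- vapply(dists, function(d) {
    vals <- vapply(acc, function(a) {
      if (as.character(d) %in% names(a)) a[[as.character(d)]] else NA_real_
    }, numeric(1))
    c(mean(vals, na.rm = TRUE),
      stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
      sum(!is.na(vals)))
  }, numeric(4))
  data.frame(distance = dists, mean = curve[1, ], lo = curve[2, ],
             hi = curve[3, ], n_iter_obs = curve[4, ])
}

#' Azimuth vs elevation modulation on virtual isotropic arrays
#'
#' Because azimuth and elevation are sampled at different resolutions, the
#' comparison is made on the 9 virtual 40 x 40 deg sub-arrays (see
#' [virtual_isotropic_arrays()]). On each sub-array a per-bouton two-way
#' fixed-effects ANOVA (azimuth x elevation) is run on trial responses; the
#' fractions of boutons significant for azimuth, elevation and their
#' interaction are averaged across sub-arrays.
#'
#' @param responses ROI x trial matrix.
#' @param log matching stimulus log rows.
#' @param geometry the full (13 x 3) `array_geometry`.
#' @param alpha significance level (default 0.05).
#' @return list with `fractions` (named: azimuth, elevation, interaction)
#'   and `per_array` (sub-array x effect matrix of fractions).
#' @export
azimuth_elevation_fractions <- function(responses, log, geometry,
                                        alpha = 0.05) {
  subs <- virtual_isotropic_arrays(geometry)
  per_array <- t(vapply(subs, function(g) {
    sel <- log$azimuth %in% g$azimuths & log$elevation %in% g$elevations
    if (sum(sel) < 18) stop("insufficient trials per virtual-array cell")
    az <- factor(log$azimuth[sel]); el <- factor(log$elevation[sel])
    sig <- vapply(seq_len(nrow(responses)), function(i) {
      p <- stats::anova(stats::lm(responses[i, sel] ~ az * el))[["Pr(>F)"]][1:3]
      p < alpha
    }, logical(3))
    rowMeans(sig)
  }, numeric(3)))
  colnames(per_array) <- c("azimuth", "elevation", "interaction")
  list(fractions = colMeans(per_array), per_array = per_array)
}

#' Onset/offset response classification
#'
#' Uses the deconvolved-event channel. The best position is the one with the
#' largest median event activity from stimulus onset to 1 s after offset.
#' At that position, a bouton is an onset unit if event rates during the
#' stimulus window significantly exceed the 1 s pre-onset baseline
#' (two-sided paired Wilcoxon signed-rank, level `alpha`), and an offset
#' unit if the 1 s post-offset window exceeds baseline while the stimulus
#' window does not differ from it.
#'
#' @param tensor a `trial_tensor` with an event channel.
#' @param modality restrict to trials of this modality (`NULL` = all).
#' @param stim_duration stimulus duration, s.
#' @param alpha test level (default 0.01).
#' @return data.frame per ROI: `roi_id`, `class` in
#'   `c("onset", "offset", "none")`, `best_azimuth`, `best_elevation`.
#' @export
classify_onset_offset <- function(tensor, modality = NULL,
                                  stim_duration = 1, alpha = 0.01) {
  if (is.null(tensor$events)) stop("tensor has no event channel")
  tr <- .modality_trials(tensor$log, modality)
  base <- trial_response(tensor, c(-1, 0), channel = "events")[, tr, drop = FALSE]
  stim <- trial_response(tensor, c(0, stim_duration),
                         channel = "events")[, tr, drop = FALSE]
  post <- trial_response(tensor, c(stim_duration, stim_duration + 1),
                         channel = "events")[, tr, drop = FALSE]
  full <- trial_response(tensor, c(0, stim_duration + 1),
                         channel = "events")[, tr, drop = FALSE]
  pos_key <- paste(tensor$log$azimuth[tr], tensor$log$elevation[tr])
  pos_lev <- unique(pos_key)
  wtest <- function(x, y) tryCatch(
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                        exact = FALSE)$p.value),
    error = function(e) 1)
  out <- lapply(seq_len(nrow(base)), function(i) {
    med <- vapply(pos_lev, function(p) stats::median(full[i, pos_key == p]),
                  numeric(1))
    sel <- pos_key == pos_lev[which.max(med)]
    p_on <- wtest(stim[i, sel], base[i, sel])
    p_off <- wtest(post[i, sel], base[i, sel])
    cls <- "none"
    if (!is.na(p_on) && p_on < alpha &&
        mean(stim[i, sel]) > mean(base[i, sel])) {
      cls <- "onset"
    } else if (!is.na(p_off) && p_off < alpha &&
               mean(post[i, sel]) > mean(base[i, sel]) &&
               (is.na(p_on) || p_on >= alpha)) {
      cls <- "offset"
    }
    co <- strsplit(pos_lev[which.max(med)], " ")[[1]]
    data.frame(roi_id = tensor$roi_ids[i], class = cls,
               best_azimuth = as.numeric(co[1]),
               best_elevation = as.numeric(co[2]))
  })
  do.call(rbind, out)
}

#' Frequency tuning of tone responses
#'
#' A bouton is tone-responsive when the frequency eliciting its largest mean
#' response drives a significant paired t-test against matched baselines at
#' `alpha_resp` with mean response above `amp_thresh` dF/F; it is
#' frequency-tuned when additionally a one-way repeated-measures ANOVA
#' across frequencies (repetition as the within-subject block) rejects at
#' `alpha_tuned`. Tuning curves are grouped by best frequency and
#' normalized to the best response.
#'
#' @param responses ROI x trial response matrix (tone analysis window).
#' @param baselines ROI x trial matched baseline matrix.
#' @param freqs per-trial frequency labels (numeric, Hz).
#' @param alpha_resp,alpha_tuned test levels (0.01 and 0.05).
#' @param amp_thresh amplitude gate, dF/F (default 0.1).
#' @return list with `per_roi` (best frequency, p-values, flags) and
#'   `curves` (data.frame `best_freq`, `freq`, `mean_norm`).
#' @export
frequency_tuning <- function(responses, baselines, freqs, alpha_resp = 0.01,
                             amp_thresh = 0.1, alpha_tuned = 0.05) {
  f <- factor(freqs)
  if (nlevels(f) < 2) stop("need >= 2 frequencies for the tuning test")
  reps <- stats::ave(seq_along(freqs), f, FUN = seq_along)
  per <- lapply(seq_len(nrow(responses)), function(i) {
    m <- tapply(responses[i, ], f, mean)
    bf <- names(m)[which.max(m)]
    sel <- f == bf
    p_resp <- tryCatch(stats::t.test(responses[i, sel], baselines[i, sel],
                                     paired = TRUE)$p.value,
                       error = function(e) 1)
    responsive <- !is.na(p_resp) && p_resp < alpha_resp &&
      max(m) > amp_thresh
    av <- summary(stats::aov(responses[i, ] ~ f + Error(factor(reps))))
    p_tuned <- tryCatch(av[["Error: Within"]][[1]][["Pr(>F)"]][1],
                        error = function(e) NA_real_)
    data.frame(roi_id = i, best_freq = as.numeric(bf), p_resp = p_resp,
               p_tuned = p_tuned, responsive = responsive,
               tuned = responsive && !is.na(p_tuned) && p_tuned < alpha_tuned)
  })
  per <- do.call(rbind, per)
  curves <- do.call(rbind, lapply(which(per$responsive), function(i) {
    m <- tapply(responses[i, ], f, mean)
    data.frame(roi_id = i, best_freq = per$best_freq[i],
               freq = as.numeric(names(m)), mean_norm = as.numeric(m / max(m)))
  }))
  if (!is.null(curves) && nrow(curves)) {
    curves <- stats::aggregate(mean_norm ~ best_freq + freq, curves, mean)
  }
  list(per_roi = per, curves = curves)
}
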