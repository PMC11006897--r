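#' Neuropil correction
#'
#' Subtracts a scaled neuropil signal from each ROI's fluorescence:
#' `F - coefficient * Fneu`. Used for somatic recordings before dF/F.
#'
#' @param traces a `roi_traces` with a neuropil channel.
#' @param coefficient neuropil contamination coefficient (default 0.7).
#' @return a `roi_traces` with corrected `f`; `fneu` is retained.
#' @export
neuropil_correct <- function(traces, coefficient = 0.7) {
  if (is.null(traces$fneu)) stop("traces carry no neuropil channel")
  traces$f <- traces$f - coefficient * traces$fneu
  traces
}

#' Trial-align traces and compute dF/F
#'
#' Cuts the continuous traces into per-trial windows and converts to
#' dF/F = (F - F0)/F0 with F0 the mean fluorescence over the trial's
#' baseline window (default the 1 s immediately preceding stimulus onset).
#' The frame containing the onset is the first post-onset frame (relative
#' time 0); windows are half-open `[start, end)` in time relative to onset.
#'
#' @param traces a `roi_traces`.
#' @param log stimulus log data.frame with `onset_frame`.
#' @param pre_s seconds of pre-onset context to keep.
#' @param post_s seconds of post-onset context to keep.
#' @param baseline_window length-2 window (s, relative to onset) over which
#'   F0 is averaged; must precede the onset.
#' @return object of class `trial_tensor`: list with `dff` (ROI x trial x
#'   frame array), `events` (same shape, if the traces carry an event
#'   channel; raw, not dF/F), `rel_time` (frame times relative to onset, s),
#'   `f0` (ROI x trial), `log`, `frame_rate`, `baseline_window`, `roi_ids`.
#' @export
segment_dff <- function(traces, log, pre_s = 2, post_s = 3,
                        baseline_window = c(-1, 0)) {
  stopifnot(baseline_window[1] < baseline_window[2],
            baseline_window[2] <= 0, pre_s >= -baseline_window[1])
  fr <- traces$frame_rate
  offs <- seq.int(-round(pre_s * fr), round(post_s * fr) - 1L)
  rel_time <- offs / fr
  n_roi <- nrow(traces$f)
  n_tr <- nrow(log)
  idx <- outer(log$onset_frame, offs, "+")   # trial x frame-within
  if (min(idx) < 1 || max(idx) > ncol(traces$f))
    stop("trial windows fall outside the recorded traces")
  cut_one <- function(m) {
    a <- array(NA_real_, c(n_roi, n_tr, length(offs)))
    for (t in seq_len(n_tr)) a[, t, ] <- m[, idx[t, ], drop = FALSE]
    a
  }
  fwin <- cut_one(traces$f)
  bl <- rel_time >= baseline_window[1] & rel_time < baseline_window[2]
  if (!any(bl)) stop("baseline window contains no frames at this frame rate")
  f0 <- apply(fwin[, , bl, drop = FALSE], c(1, 2), mean)
  if (any(f0 <= 0)) stop("non-positive F0 encountered; invalid baseline")
  dff <- sweep(sweep(fwin, c(1, 2), f0, "-"), c(1, 2), f0, "/")
  events <- if (!is.null(traces$events)) cut_one(traces$events) else NULL
  structure(list(dff = dff, events = events, rel_time = rel_time, f0 = f0,
                 log = log, frame_rate = fr,
                 baseline_window = baseline_window,
                 roi_ids = traces$roi_ids),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat(sprintf("trial_tensor: %d ROIs x %d trials x %d frames (%.3g Hz)\n",
              dim(x$dff)[1], dim(x$dff)[2], dim(x$dff)[3], x$frame_rate))
  invisible(x)
}

#' Scalar trial responses
#'
#' Time-mean of dF/F (or the event channel) over a response window per ROI
#' per trial. The default window 0.2-1.8 s from onset is the bouton
#' response window.
#'
#' @param tensor a `trial_tensor`.
#' @param window length-2 numeric, seconds relative to onset, half-open.
#' @param channel `"dff"` or `"events"`.
#' @return ROI x trial numeric matrix.
#' @export
trial_response <- function(tensor, window = c(0.2, 1.8), channel = "dff") {
  x <- tensor[[channel]]
  if (is.null(x)) stop("tensor has no '", channel, "' channel")
  sel <- tensor$rel_time >= window[1] & tensor$rel_time < window[2]
  if (!any(sel)) stop("empty response window at this frame rate")
  apply(x[, , sel, drop = FALSE], c(1, 2), mean)
}

# paired per-trial baseline values (window-mean of dF/F over the baseline
# window); identically 0 when the baseline window equals the F0 window, in
# which case the paired tests reduce to one-sample tests of the response.
.baseline_response <- function(tensor) {
  trial_response(tensor, tensor$baseline_window)
}

# rows of `log` matching a modality (NULL = all)
.modality_trials <- function(log, modality) {
  if (is.null(modality)) seq_len(nrow(log)) else which(log$modality == modality)
}

#' Responsive-bouton selection
#'
#' A bouton is responsive if, at the position with the strongest median
#' response, (i) the paired two-sided Wilcoxon signed-rank test of trial
#' responses against matched trial baselines rejects at `alpha`, and (ii)
#' the response amplitude exceeds `amp_thresh` dF/F. With
#' `method = "bootstrap"` the test is replaced by requiring the strongest
#' median response to exceed the upper bound of the baseline's 95%
#' bootstrap confidence interval.
#'
#' @param tensor a `trial_tensor`.
#' @param modality restrict to trials of this modality (`NULL` = all).
#' @param alpha test level (default 0.01).
#' @param amp_thresh amplitude gate, dF/F (default 0.15).
#' @param window response window, s.
#' @param method `"wilcoxon"` or `"bootstrap"`.
#' @param amp_stat whether the amplitude gate uses the `"mean"` (default) or
#'   `"median"` response at the best position.
#' @param n_boot bootstrap resamples for `method = "bootstrap"`.
#' @return data.frame per ROI: `roi_id`, `best_position` (index into the
#'   modality's position set), `best_azimuth`, `best_elevation`, `p_value`,
#'   `amplitude`, `responsive`.
#' @export
select_responsive_boutons <- function(tensor, modality = NULL, alpha = 0.01,
                                      amp_thresh = 0.15,
                                      window = c(0.2, 1.8),
                                      method = c("wilcoxon", "bootstrap"),
                                      amp_stat = c("mean", "median"),
                                      n_boot = 1000) {
  method <- match.arg(method)
  amp_stat <- match.arg(amp_stat)
  tr <- .modality_trials(tensor$log, modality)
  resp <- trial_response(tensor, window)[, tr, drop = FALSE]
  base <- .baseline_response(tensor)[, tr, drop = FALSE]
  pos_key <- paste(tensor$log$azimuth[tr], tensor$log$elevation[tr])
  pos_lev <- unique(pos_key)
  if (min(table(pos_key)) < 2) stop("need >= 2 trials per position")
  out <- lapply(seq_len(nrow(resp)), function(i) {
    med <- vapply(pos_lev, function(p) stats::median(resp[i, pos_key == p]),
                  numeric(1))
    bp <- which.max(med)
    sel <- pos_key == pos_lev[bp]
    x <- resp[i, sel]; y <- base[i, sel]
    amp <- if (amp_stat == "mean") mean(x) else stats::median(x)
    if (method == "wilcoxon") {
      p <- tryCatch(
        suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = FALSE)$p.value),
        error = function(e) 1)
      ok <- !is.na(p) && p < alpha
    } else {
      bb <- as.vector(base[i, ])
      bmed <- vapply(seq_len(n_boot), function(k)
        stats::median(sample(bb, length(x), replace = TRUE)), numeric(1))
      p <- NA_real_
      ok <- med[bp] > stats::quantile(bmed, 0.975)
    }
    co <- strsplit(pos_lev[bp], " ")[[1]]
    data.frame(roi_id = tensor$roi_ids[i], best_position = bp,
               best_azimuth = as.numeric(co[1]),
               best_elevation = as.numeric(co[2]),
               p_value = p, amplitude = amp,
               responsive = ok && amp > amp_thresh)
  })
  do.call(rbind, out)
}

#' Somatic inclusion and responsiveness filters
#'
#' Somata are kept when their mean trial-baseline fluorescence exceeds the
#' surrounding neuropil by more than `neuropil_margin` (3% by default), and
#' considered responsive when their best trial type elicits a significant
#' paired t-test (response vs matched baseline, `p < p_thresh`) with mean
#' response above `amp_thresh` dF/F.
#'
#' @param traces the uncorrected `roi_traces` (with `fneu`).
#' @param tensor a `trial_tensor` computed from the (neuropil-corrected)
#'   traces; its log defines the trial types (position x modality).
#' @param neuropil_margin fractional margin over neuropil (default 0.03).
#' @param p_thresh response test level (default 0.05).
#' @param amp_thresh response amplitude gate, dF/F (default 0.05).
#' @param window response window, s (default first frame after onset to
#'   first frame after offset, approximated by \[0, 1\]).
#' @return data.frame per ROI: `roi_id`, `above_neuropil`, `p_value`,
#'   `amplitude`, `included`.
#' @export
select_somata <- function(traces, tensor, neuropil_margin = 0.03,
                          p_thresh = 0.05, amp_thresh = 0.05,
                          window = c(0, 1)) {
  if (is.null(traces$fneu)) stop("traces carry no neuropil channel")
  fr <- traces$frame_rate
  bl_off <- seq.int(round(tensor$baseline_window[1] * fr),
                    round(tensor$baseline_window[2] * fr) - 1L)
  bidx <- as.vector(outer(tensor$log$onset_frame, bl_off, "+"))
  f_base <- rowMeans(traces$f[, bidx, drop = FALSE])
  neu_base <- rowMeans(traces$fneu[, bidx, drop = FALSE])
  above <- f_base > (1 + neuropil_margin) * neu_base
  resp <- trial_response(tensor, window)
  base <- .baseline_response(tensor)
  type <- paste(tensor$log$modality, tensor$log$azimuth, tensor$log$elevation)
  lev <- unique(type)
  out <- lapply(seq_len(nrow(resp)), function(i) {
    m <- vapply(lev, function(p) mean(resp[i, type == p]), numeric(1))
    bt <- which.max(m)
    sel <- type == lev[bt]
    p <- tryCatch(stats::t.test(resp[i, sel], base[i, sel],
                                paired = TRUE)$p.value,
                  error = function(e) 1)
    data.frame(roi_id = tensor$roi_ids[i], above_neuropil = above[i],
               p_value = p, amplitude = m[bt],
               included = above[i] && !is.na(p) && p < p_thresh &&
                 m[bt] > amp_thresh)
  })
  do.call(rbind, out)
}
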