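#' Population visual response map of V1 somata
#'
#' Baseline-subtracted responses (dF/F are baseline-referenced by
#' construction) are averaged across neurons and repetitions and
#' time-averaged over the stimulus window, giving the mean population
#' response R(az, el) at each LED position.
#'
#' @param tensor a `trial_tensor` of the somatic session.
#' @param geometry an `array_geometry`.
#' @param modality stimulus modality to map (default `"visual"`).
#' @param window response window, s (default the 1 s stimulus).
#' @return data.frame with `azimuth`, `elevation`, `response`.
#' @export
population_response_map <- function(tensor, geometry, modality = "visual",
                                    window = c(0, 1)) {
  tr <- .modality_trials(tensor$log, modality)
  if (!length(tr)) stop("no trials of the requested modality")
  resp <- trial_response(tensor, window)[, tr, drop = FALSE]
  maps <- response_map(resp, tensor$log[tr, ], geometry)
  data.frame(azimuth = geometry$positions$azimuth,
             elevation = geometry$positions$elevation,
             response = colMeans(maps))
}

#' Elliptical 2D Gaussian receptive-field fit
#'
#' Least-squares fit of an elliptical 2D Gaussian with amplitude, center,
#' two axis widths, orientation and offset to a position-response map,
#' using Levenberg-Marquardt with bounds. Initialization is at the map's
#' response-weighted centroid with range-based widths; on failure the fit
#' restarts from jittered starts. The fitted center is the RF location.
#'
#' @param map data.frame with `azimuth`, `elevation`, `response` (e.g. from
#'   [population_response_map()]).
#' @param n_restarts maximum jittered restarts after a failed fit.
#' @return object of class `rf_fit`: list with `center` (azimuth,
#'   elevation), `widths` (two s.d., degrees), `orientation_deg`,
#'   `amplitude`, `offset`, `residual_norm`, `converged`, `reliable`
#'   (`FALSE` when the fitted amplitude is negligible against the residual
#'   scale, i.e. a flat map).
#' @export
fit_rf_gaussian <- function(map, n_restarts = 5) {
  x <- map$azimuth; y <- map$elevation; z <- map$response
  wpos <- pmax(z - min(z), 0)
  if (sum(wpos) == 0) wpos <- rep(1, length(z))
  cx0 <- sum(x * wpos) / sum(wpos)
  cy0 <- sum(y * wpos) / sum(wpos)
  span_x <- max(diff(range(x)), 10); span_y <- max(diff(range(y)), 10)
  start0 <- c(A = max(z) - min(z), x0 = cx0, y0 = cy0,
              sx = span_x / 4, sy = span_y / 4, th = 0, b = min(z))
  lower <- c(A = 0, x0 = min(x) - 20, y0 = min(y) - 20, sx = 1, sy = 1,
             th = -pi / 2, b = min(z) - abs(min(z)) - 1)
  upper <- c(A = 10 * max(abs(z)) + 1, x0 = max(x) + 20, y0 = max(y) + 20,
             sx = 4 * span_x, sy = 4 * span_y, th = pi / 2,
             b = max(z) + abs(max(z)) + 1)
  gauss2d <- function(p, x, y) {
    ct <- cos(p["th"]); st <- sin(p["th"])
    u <- ct * (x - p["x0"]) + st * (y - p["y0"])
    v <- -st * (x - p["x0"]) + ct * (y - p["y0"])
    p["b"] + p["A"] * exp(-(u^2 / (2 * p["sx"]^2) + v^2 / (2 * p["sy"]^2)))
  }
  fit1 <- function(start) {
    tryCatch(
      minpack.lm::nls.lm(par = start,
                         fn = function(p) z - gauss2d(p, x, y),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- fit1(start0)
  set.seed(42)
  tries <- 0
  while ((is.null(fit) || fit$info < 1 || fit$info > 4) &&
         tries < n_restarts) {
    tries <- tries + 1
    jit <- start0
    jit["x0"] <- stats::runif(1, min(x), max(x))
    jit["y0"] <- stats::runif(1, min(y), max(y))
    jit["sx"] <- stats::runif(1, span_x / 8, span_x / 2)
    jit["sy"] <- stats::runif(1, span_y / 8, span_y / 2)
    fit <- fit1(jit)
  }
  if (is.null(fit)) {
    return(structure(list(center = list(azimuth = NA_real_,
                                        elevation = NA_real_),
                          widths = c(NA_real_, NA_real_),
                          orientation_deg = NA_real_, amplitude = NA_real_,
                          offset = NA_real_, residual_norm = NA_real_,
                          converged = FALSE, reliable = FALSE),
                     class = "rf_fit"))
  }
  p <- stats::coef(fit)
  resid_norm <- sqrt(sum(fit$fvec^2))
  resid_scale <- stats::sd(fit$fvec)
  reliable <- is.finite(p["A"]) &&
    p["A"] > max(4 * resid_scale, 1e-6 * max(1, max(abs(z))))
  structure(list(center = list(azimuth = unname(p["x0"]),
                               elevation = unname(p["y0"])),
                 widths = unname(p[c("sx", "sy")]),
                 orientation_deg = unname(p["th"]) * 180 / pi,
                 amplitude = unname(p["A"]), offset = unname(p["b"]),
                 residual_norm = resid_norm,
                 converged = fit$info >= 1 && fit$info <= 4,
                 reliable = unname(reliable)),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf(paste0("rf_fit: center (%.1f, %.1f) deg, widths (%.1f, %.1f)",
                     " deg, amplitude %.3g%s\n"),
              x$center$azimuth, x$center$elevation, x$widths[1], x$widths[2],
              x$amplitude, if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}

#' Population RF of a somatic session
#'
#' Convenience wrapper: [population_response_map()] followed by
#' [fit_rf_gaussian()].
#'
#' @inheritParams population_response_map
#' @return an `rf_fit`.
#' @export
population_rf <- function(tensor, geometry, modality = "visual",
                          window = c(0, 1)) {
  fit_rf_gaussian(population_response_map(tensor, geometry, modality, window))
}

#' Retinotopic-alignment regression
#'
#' Ordinary least squares of session best auditory azimuth on the session's
#' V1 population RF azimuth center, with residual-bootstrap 95% confidence
#' intervals (residuals resampled with replacement, model refit). A slope
#' interval excluding 0 indicates topographic alignment of auditory
#' preferences with V1 retinotopy.
#'
#' @param best_azimuths per-session best auditory azimuth, degrees.
#' @param rf_centers per-session V1 RF azimuth center, degrees.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list with `slope`, `intercept`, `slope_ci`, `intercept_ci`,
#'   `fit` (the `lm`).
#' @export
retinotopy_regression <- function(best_azimuths, rf_centers, n_boot = 1000,
                                  seed = 1) {
  stopifnot(length(best_azimuths) == length(rf_centers))
  if (length(best_azimuths) < 3) stop("need >= 3 sessions")
  if (stats::var(rf_centers) == 0) stop("degenerate predictor: RF centers all equal")
  fit <- stats::lm(best_azimuths ~ rf_centers)
  res <- stats::residuals(fit)
  fitted <- stats::fitted(fit)
  set.seed(seed)
  boot <- t(vapply(seq_len(n_boot), function(b) {
    yb <- fitted + sample(res, replace = TRUE)
    stats::coef(stats::lm(yb ~ rf_centers))
  }, numeric(2)))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_ci = stats::quantile(boot[, 2], c(0.025, 0.975), names = FALSE),
       intercept_ci = stats::quantile(boot[, 1], c(0.025, 0.975),
                                      names = FALSE),
       fit = fit)
}

#' Decoding error versus distance from the V1 RF center
#'
#' Single-trial decoding errors are grouped in bins (10 degrees by default)
#' of the absolute difference between the stimulus azimuth and the
#' session's V1 population RF azimuth center. A shuffle-subtracted profile
#' is returned when shuffle trials are provided. Empty bins are reported as
#' missing, not zero.
#'
#' @param trials `decode_result$trials` data.frame.
#' @param geometry the `array_geometry` the trial indices refer to.
#' @param rf_center_az V1 RF azimuth center, degrees.
#' @param bin_width bin width, degrees (default 10).
#' @param shuffle_trials optional data.frame like `trials` from decoding a
#'   label-shuffled session.
#' @return data.frame with `bin_lo`, `bin_hi`, `mean_error`, `n_trials`,
#'   and when shuffles are given `shuffle_error`, `error_minus_shuffle`.
#' @export
error_vs_rf_distance <- function(trials, geometry, rf_center_az,
                                 bin_width = 10, shuffle_trials = NULL) {
  dist <- abs(geometry$positions$azimuth[trials$true_idx] - rf_center_az)
  bin <- floor(dist / bin_width)
  agg <- stats::aggregate(trials$error_deg, list(bin = bin),
                          function(v) c(mean(v), length(v)))
  out <- data.frame(bin_lo = agg$bin * bin_width,
                    bin_hi = (agg$bin + 1) * bin_width,
                    mean_error = agg$x[, 1], n_trials = agg$x[, 2])
  if (!is.null(shuffle_trials)) {
    sd_ <- abs(geometry$positions$azimuth[shuffle_trials$true_idx] -
                 rf_center_az)
    sb <- floor(sd_ / bin_width)
    sh <- tapply(shuffle_trials$error_deg, sb, mean)
    out$shuffle_error <- as.numeric(sh[as.character(agg$bin)])
    out$error_minus_shuffle <- out$mean_error - out$shuffle_error
  }
  out
}

#' Decoding error versus V1 retinotopic position
#'
#' To compare sessions recorded at different retinotopic positions without
#' a population-size confound, each session is subsampled to `n_min` axons
#' (`n_draws` random draws, errors averaged), and the session errors are
#' smoothed with a moving average over a `window`-degree span of RF azimuth
#' in `step`-degree steps.
#'
#' @param sessions list of sessions, each a list with `responses` (axon x
#'   trial), `labels`, `geometry`, `rf_az` (session RF azimuth center).
#' @param n_min axons per subsample; default the minimum pool size across
#'   sessions.
#' @param n_draws random draws per session (default 10).
#' @param window,step moving-average span and step, degrees (20 and 5).
#' @param k folds for the inner cross-validated decoder.
#' @param seed integer seed.
#' @return list with `sessions` (data.frame `rf_az`, `mean_error`) and
#'   `curve` (data.frame `center_az`, `mean_error`, `n_sessions`).
#' @export
error_vs_retinotopic_position <- function(sessions, n_min = NULL,
                                          n_draws = 10, window = 20,
                                          step = 5, k = 5, seed = 1) {
  if (length(sessions) < 2) stop("need >= 2 sessions")
  pools <- vapply(sessions, function(s) nrow(s$responses), integer(1))
  if (is.null(n_min)) n_min <- min(pools)
  if (n_min > min(pools)) stop("n_min larger than the smallest axon pool")
  per <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    errs <- vapply(seq_len(n_draws), function(j) {
      set.seed(seed + 1000L * i + j)
      take <- sample.int(nrow(s$responses), n_min)
      crossval_decode(s$responses[take, , drop = FALSE], s$labels,
                      s$geometry, k = k, seed = seed + j,
                      min_axons = 0)$mean_error
    }, numeric(1))
    data.frame(rf_az = s$rf_az, mean_error = mean(errs))
  }))
  centers <- seq(min(per$rf_az), max(per$rf_az), by = step)
  curve <- do.call(rbind, lapply(centers, function(cz) {
    sel <- abs(per$rf_az - cz) <= window / 2
    if (!any(sel)) return(NULL)
    data.frame(center_az = cz, mean_error = mean(per$mean_error[sel]),
               n_sessions = sum(sel))
  }))
  list(sessions = per, curve = curve)
}
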