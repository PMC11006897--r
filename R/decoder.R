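#' Fit the Gaussian observation model of the naive Bayes decoder
#'
#' For every axon i and stimulus position s the training trials give a
#' response mean `R[i,s]` and standard deviation `sigma[i,s]` (n-1
#' denominator); the single-trial likelihood of a response r is the normal
#' density at (R, sigma). Standard deviations are floored at `sigma_floor`
#' because the density is undefined at sigma = 0 (constant training
#' responses).
#'
#' @param responses axon x trial training matrix.
#' @param labels integer position index per training trial (columns).
#' @param n_pos total number of positions in the geometry.
#' @param sigma_floor minimum sigma, dF/F units (default 1e-3).
#' @return object of class `gaussian_response_model`: list with `mean` and
#'   `sd` (axon x position matrices), `n_pos`, `sigma_floor`.
#' @export
fit_decoder <- function(responses, labels, n_pos, sigma_floor = 1e-3) {
  stopifnot(ncol(responses) == length(labels), sigma_floor > 0)
  cnt <- tabulate(labels, n_pos)
  if (any(cnt < 2)) stop("every position needs >= 2 training trials")
  mu <- matrix(NA_real_, nrow(responses), n_pos)
  sd_ <- matrix(NA_real_, nrow(responses), n_pos)
  for (s in seq_len(n_pos)) {
    x <- responses[, labels == s, drop = FALSE]
    mu[, s] <- rowMeans(x)
    sd_[, s] <- sqrt(rowSums((x - mu[, s])^2) / (ncol(x) - 1))
  }
  sd_ <- pmax(sd_, sigma_floor)
  structure(list(mean = mu, sd = sd_, n_pos = n_pos,
                 sigma_floor = sigma_floor),
            class = "gaussian_response_model")
}

#' Per-position log-likelihoods of population responses
#'
#' Under conditional independence of axons given the stimulus, the
#' log-likelihood of a population response vector at position s is the sum
#' over axons of the Gaussian log-density of each axon's response under its
#' (mean, sd) for s. No prior or evidence term enters: both are constant in
#' the argmax over positions.
#'
#' @param model a `gaussian_response_model`.
#' @param responses axon x trial matrix of responses to score (a single
#'   trial may be given as a vector).
#' @return trial x position matrix of log-likelihoods.
#' @export
log_likelihood <- function(model, responses) {
  if (is.null(dim(responses))) responses <- matrix(responses, ncol = 1)
  if (nrow(responses) != nrow(model$mean))
    stop("response dimension does not match the model's axon count")
  if (ncol(responses) == 0) return(matrix(numeric(0), 0, model$n_pos))
  ll <- vapply(seq_len(model$n_pos), function(s) {
    colSums(stats::dnorm(responses, model$mean[, s], model$sd[, s],
                         log = TRUE))
  }, numeric(ncol(responses)))
  matrix(ll, nrow = ncol(responses))
}

# argmax with exact ties broken uniformly at random
.argmax_tiebreak <- function(ll) {
  apply(ll, 1, function(v) {
    w <- which(v >= max(v) - 1e-12)
    if (length(w) == 1) w else w[sample.int(length(w), 1)]
  })
}

#' Decode single trials by maximum likelihood
#'
#' The decoded position is the argmax of the per-position log-likelihood;
#' exact ties are broken uniformly at random under `tie_seed`. The decoding
#' error is the Euclidean angular distance between the true and decoded
#' positions.
#'
#' @param model a `gaussian_response_model`.
#' @param responses axon x trial matrix (or single-trial vector).
#' @param true_idx integer true position index per trial (optional).
#' @param geometry an `array_geometry` (needed for errors).
#' @param tie_seed seed for tie breaking.
#' @return data.frame with `decoded_idx`, and when `true_idx` is supplied,
#'   `true_idx` and `error_deg`; the log-likelihood matrix is attached as
#'   attribute `"log_likelihood"`.
#' @export
decode_trials <- function(model, responses, true_idx = NULL,
                          geometry = NULL, tie_seed = 1) {
  ll <- log_likelihood(model, responses)
  set.seed(tie_seed)
  dec <- .argmax_tiebreak(ll)
  out <- data.frame(decoded_idx = dec)
  if (!is.null(true_idx)) {
    out$true_idx <- true_idx
    if (is.null(geometry)) stop("geometry needed to compute errors")
    out$error_deg <- angular_distance(geometry$positions[dec, ],
                                      geometry$positions[true_idx, ])
  }
  attr(out, "log_likelihood") <- ll
  out
}

# stratified fold assignment: within each position, shuffled trials are
# dealt round-robin over folds so every fold trains on every position
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (s in unique(labels)) {
    tr <- which(labels == s)
    fold[tr[sample.int(length(tr))]] <- rep_len(seq_len(k), length(tr))
  }
  fold
}

# mean error per true position, then across positions
.position_averaged_error <- function(true_idx, error) {
  mean(tapply(error, true_idx, mean))
}

#' Cross-validated population decoding
#'
#' Stratified k-fold cross-validation (default 5-fold: 80% of trials train
#' the decoder, the held-out 20% are decoded, rotating so every trial is
#' decoded exactly once). The summary error is averaged over trials per
#' true position, then across positions. Sessions with `min_axons` axons or
#' fewer are skipped (too few units for the population decoder).
#'
#' @param responses axon x trial matrix.
#' @param labels integer position index per trial.
#' @param geometry an `array_geometry`.
#' @param k number of folds (default 5).
#' @param seed integer seed (fold assignment and tie breaks).
#' @param min_axons minimum axon count; at or below it the session is
#'   skipped (default 10). Set to 0 to disable.
#' @param sigma_floor passed to [fit_decoder()].
#' @return object of class `decode_result`: list with `trials` (data.frame
#'   `trial`, `true_idx`, `decoded_idx`, `error_deg`, `fold`),
#'   `mean_error` (position-averaged), `per_position` (data.frame), and
#'   `skipped` flag with `reason`.
#' @export
crossval_decode <- function(responses, labels, geometry, k = 5, seed = 1,
                            min_axons = 10, sigma_floor = 1e-3) {
  if (nrow(responses) <= min_axons) {
    return(structure(list(skipped = TRUE,
                          reason = sprintf("only %d axons (need > %d)",
                                           nrow(responses), min_axons)),
                     class = "decode_result"))
  }
  set.seed(seed)
  fold <- .stratified_folds(labels, k)
  res <- vector("list", k)
  for (f in seq_len(k)) {
    train <- fold != f
    if (all(train)) next   # a fold can be empty when reps < folds
    model <- fit_decoder(responses[, train, drop = FALSE], labels[train],
                         n_positions(geometry), sigma_floor)
    d <- decode_trials(model, responses[, !train, drop = FALSE],
                       labels[!train], geometry,
                       tie_seed = seed + f)
    d$trial <- which(!train)
    d$fold <- f
    res[[f]] <- d
  }
  trials <- do.call(rbind, res)
  trials <- trials[order(trials$trial),
                   c("trial", "true_idx", "decoded_idx", "error_deg", "fold")]
  rownames(trials) <- NULL
  per_pos <- stats::aggregate(error_deg ~ true_idx, trials, mean)
  structure(list(trials = trials,
                 mean_error = mean(per_pos$error_deg),
                 per_position = per_pos, skipped = FALSE),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("decode_result: skipped (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("decode_result: %d trials, mean error %.2f deg\n",
                nrow(x$trials), x$mean_error))
  }
  invisible(x)
}

#' Shuffle null distribution of decoding errors
#'
#' Position labels are permuted across trials and the full cross-validated
#' decoding repeated, `n_shuffles` times; the per-shuffle position-averaged
#' mean errors form the null distribution against which observed errors are
#' compared.
#'
#' @inheritParams crossval_decode
#' @param n_shuffles number of label permutations (default 100).
#' @return numeric vector of per-shuffle mean errors.
#' @export
shuffle_null <- function(responses, labels, geometry, k = 5,
                         n_shuffles = 100, seed = 1, min_axons = 10,
                         sigma_floor = 1e-3) {
  vapply(seq_len(n_shuffles), function(j) {
    set.seed(seed + 7919L * j)
    perm <- sample(labels)
    r <- crossval_decode(responses, perm, geometry, k = k,
                         seed = seed + j, min_axons = min_axons,
                         sigma_floor = sigma_floor)
    if (isTRUE(r$skipped)) NA_real_ else r$mean_error
  }, numeric(1))
}

#' Decoding error versus number of axons
#'
#' For each population size n, draws n axons without replacement from the
#' pool (not to violate the independence assumption), runs the
#' cross-validated decoder, and repeats `n_iter` times to give the mean and
#' 95% interval of the error. When n equals the pool size there is a single
#' possible draw and the interval has zero width.
#'
#' @inheritParams crossval_decode
#' @param n_grid vector of population sizes.
#' @param n_iter repetitions per size (default 100).
#' @return data.frame with `n_axons`, `mean_error`, `lo`, `hi`.
#' @export
error_vs_n_axons <- function(responses, labels, geometry, n_grid,
                             n_iter = 100, k = 5, seed = 1,
                             sigma_floor = 1e-3) {
  pool <- nrow(responses)
  if (max(n_grid) > pool) stop("n exceeds the axon pool")
  out <- lapply(n_grid, function(n) {
    iters <- if (n == pool) 1L else n_iter
    errs <- vapply(seq_len(iters), function(j) {
      set.seed(seed + 104729L * n + j)
      take <- sample.int(pool, n)
      crossval_decode(responses[take, , drop = FALSE], labels, geometry,
                      k = k, seed = seed + j, min_axons = 0,
                      sigma_floor = sigma_floor)$mean_error
    }, numeric(1))
    data.frame(n_axons = n, mean_error = mean(errs),
               lo = stats::quantile(errs, 0.025, names = FALSE),
               hi = stats::quantile(errs, 0.975, names = FALSE))
  })
  do.call(rbind, out)
}

#' Leave-one-out decoding
#'
#' Each trial is decoded from a model trained on all other trials
#' (deterministic folds); otherwise identical to [crossval_decode()]. Used
#' for the somatic audiovisual decoding where repetition counts are small.
#'
#' @inheritParams crossval_decode
#' @return a `decode_result`.
#' @export
loo_decode <- function(responses, labels, geometry, sigma_floor = 1e-3,
                       tie_seed = 1) {
  if (min(tabulate(labels, n_positions(geometry))) < 3)
    stop("every position needs >= 3 trials for leave-one-out decoding")
  n_tr <- ncol(responses)
  res <- lapply(seq_len(n_tr), function(t) {
    model <- fit_decoder(responses[, -t, drop = FALSE], labels[-t],
                         n_positions(geometry), sigma_floor)
    d <- decode_trials(model, responses[, t], labels[t], geometry,
                       tie_seed = tie_seed + t)
    d$trial <- t
    d$fold <- t
    d
  })
  trials <- do.call(rbind, res)[, c("trial", "true_idx", "decoded_idx",
                                    "error_deg", "fold")]
  per_pos <- stats::aggregate(error_deg ~ true_idx, trials, mean)
  structure(list(trials = trials, mean_error = mean(per_pos$error_deg),
                 per_position = per_pos, skipped = FALSE),
            class = "decode_result")
}
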