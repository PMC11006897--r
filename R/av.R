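#' Trial responses of an audiovisual session
#'
#' Segments the session traces and returns the neuron x trial response
#' matrix over the stimulus window, alongside the trial table.
#'
#' @param session list from [simulate_av_session()] (or any list with
#'   `traces` and `stim_log`).
#' @param window response window, s (default the 1 s stimulus).
#' @param pre_s,post_s segmentation context, s.
#' @return list with `responses` (neuron x trial), `trials` (the stimulus
#'   log), `tensor`.
#' @export
av_trial_responses <- function(session, window = c(0, 1), pre_s = 1,
                               post_s = 2) {
  tensor <- segment_dff(session$traces, session$stim_log, pre_s = pre_s,
                        post_s = post_s, baseline_window = c(-1, 0))
  list(responses = trial_response(tensor, window), trials = session$stim_log,
       tensor = tensor)
}

#' Audiovisual enhancement of visual responses
#'
#' Per neuron, condition means are computed with AV trials averaged across
#' speaker offsets (and intensity levels); the enhancement is reported both
#' as the difference AV - V and the ratio AV / V. The population statistic
#' is a two-sided paired t-test of AV vs V across mouse-level means (the
#' repeated-measures subject is the mouse); it requires at least two mice.
#'
#' @param responses neuron x trial matrix.
#' @param trials trial table with `condition` in `c("A","V","AV")` and
#'   `offset`.
#' @param mouse per-neuron mouse label (recycled scalar for one session).
#' @return list with `per_neuron` (data.frame `mouse`, `v`, `av`, `diff`,
#'   `ratio`), `per_mouse`, and `test` (paired t `htest`, or `NULL` with
#'   fewer than two mice).
#' @export
av_enhancement <- function(responses, trials, mouse = "m1") {
  if (!all(c("V", "AV") %in% trials$condition)) stop("missing condition")
  mouse <- rep_len(mouse, nrow(responses))
  v <- rowMeans(responses[, trials$condition == "V", drop = FALSE])
  av <- rowMeans(responses[, trials$condition == "AV", drop = FALSE])
  per_neuron <- data.frame(mouse = mouse, v = v, av = av, diff = av - v,
                           ratio = av / v)
  per_mouse <- data.frame(
    mouse = unique(mouse),
    v = as.numeric(tapply(v, mouse, mean)[unique(mouse)]),
    av = as.numeric(tapply(av, mouse, mean)[unique(mouse)]))
  test <- NULL
  if (nrow(per_mouse) >= 2) {
    test <- stats::t.test(per_mouse$av, per_mouse$v, paired = TRUE)
  }
  list(per_neuron = per_neuron, per_mouse = per_mouse, test = test)
}

#' AV modulation as a function of speaker-LED offset
#'
#' Aggregates neuron responses to mouse-level condition means per speaker
#' offset (speakers offset in elevation are excluded when an
#' `offset_elevation` column is present) and tests the offset dependence of
#' the AV response with a repeated-measures ANOVA on mouse means (mouse as
#' the subject; intensity factors enter when they vary).
#'
#' @inheritParams av_enhancement
#' @return list with `per_offset` (mouse x offset AV and A means, plus the
#'   AV/V ratio using each mouse's V mean), `anova` (the aov summary) and
#'   `offset_p` (p-value of the offset effect).
#' @export
modulation_vs_offset <- function(responses, trials, mouse = "m1") {
  if (!is.null(trials$offset_elevation)) {
    keep <- is.na(trials$offset_elevation) | trials$offset_elevation == 0
    responses <- responses[, keep, drop = FALSE]
    trials <- trials[keep, , drop = FALSE]
  }
  offsets <- sort(unique(trials$offset[trials$condition == "AV"]))
  if (length(offsets) < 2) stop("need >= 2 speaker offsets")
  mouse <- rep_len(mouse, nrow(responses))
  mice <- unique(mouse)
  rows <- list()
  for (m in mice) {
    nr <- mouse == m
    v_mean <- mean(responses[nr, trials$condition == "V", drop = FALSE])
    for (o in offsets) {
      av_sel <- trials$condition == "AV" & trials$offset == o
      a_sel <- trials$condition == "A" & trials$offset == o
      rows[[length(rows) + 1L]] <- data.frame(
        mouse = m, offset = o,
        av = mean(responses[nr, av_sel, drop = FALSE]),
        a = mean(responses[nr, a_sel, drop = FALSE]),
        av_over_v = mean(responses[nr, av_sel, drop = FALSE]) / v_mean)
    }
  }
  per_offset <- do.call(rbind, rows)
  anova_sum <- NULL; offset_p <- NA_real_
  if (length(mice) >= 2) {
    d <- per_offset
    d$offset <- factor(d$offset); d$mouse <- factor(d$mouse)
    fit <- stats::aov(av ~ offset + Error(mouse / offset), data = d)
    anova_sum <- summary(fit)
    tab <- anova_sum[["Error: mouse:offset"]][[1]]
    offset_p <- tab[["Pr(>F)"]][1]
  } else {
    # single session: offset effect across neurons (fixed effects)
    nm <- lapply(offsets, function(o) {
      rowMeans(responses[, trials$condition == "AV" & trials$offset == o,
                         drop = FALSE])
    })
    d <- data.frame(y = unlist(nm),
                    offset = factor(rep(offsets, each = nrow(responses))),
                    neuron = factor(rep(seq_len(nrow(responses)),
                                        length(offsets))))
    fit <- stats::aov(y ~ offset + Error(neuron), data = d)
    anova_sum <- summary(fit)
    tab <- anova_sum[["Error: Within"]][[1]]
    offset_p <- tab[["Pr(>F)"]][1]
  }
  list(per_offset = per_offset, anova = anova_sum, offset_p = offset_p)
}

#' Decoding the speaker offset from somatic responses
#'
#' Applies the maximum-likelihood decoder (leave-one-out cross-validation)
#' to A-only and AV trials separately, with the azimuthal speaker offsets
#' as the position set and a label-permutation shuffle null. All neurons
#' are included.
#'
#' @inheritParams av_enhancement
#' @param n_shuffles label permutations for the null (default 100).
#' @param seed integer seed.
#' @return named list (`A`, `AV`) of lists with `result` (a
#'   `decode_result`), `shuffle_errors`, `chance` (enumerated chance error
#'   of the offset geometry).
#' @export
decode_offset_from_somata <- function(responses, trials, n_shuffles = 100,
                                      seed = 1) {
  offsets <- sort(unique(trials$offset[!is.na(trials$offset)]))
  geom <- array_geometry(azimuths = offsets, elevations = 0)
  run <- function(cond) {
    sel <- trials$condition == cond
    labels <- match(trials$offset[sel], offsets)
    resp <- responses[, sel, drop = FALSE]
    res <- loo_decode(resp, labels, geom, tie_seed = seed)
    sh <- vapply(seq_len(n_shuffles), function(j) {
      set.seed(seed + 31L * j)
      loo_decode(resp, sample(labels), geom,
                 tie_seed = seed + j)$mean_error
    }, numeric(1))
    list(result = res, shuffle_errors = sh, chance = chance_error(geom))
  }
  list(A = run("A"), AV = run("AV"))
}
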