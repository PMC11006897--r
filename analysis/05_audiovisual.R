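#!/usr/bin/env Rscript
# Audiovisual modulation of V1 somata: sound enhances visual responses
# multiplicatively (gain 1.5 in the generative model), independent of the
# speaker-LED offset, and the offset itself is not decodable from the
# population.

suppressPackageStartupMessages(library(audiospace))
dir.create("results", showWarnings = FALSE)

n_mice <- 3
sessions <- lapply(seq_len(n_mice), function(m) {
  sc <- session_config(n_reps = 7, noise_sd = 0.05, trial_gain_sd = 0.25,
                       indicator_tau = 0.4, seed = 5000 + m)
  simulate_av_session(av_gain = 1.5, config = sc, n_neurons = 25,
                      mouse = paste0("m", m))
})

per_mouse <- do.call(rbind, lapply(seq_len(n_mice), function(m) {
  tr <- av_trial_responses(sessions[[m]])
  av_enhancement(tr$responses, tr$trials, mouse = paste0("m", m))$per_mouse
}))
tt <- t.test(per_mouse$av, per_mouse$v, paired = TRUE)
cat(sprintf("AV vs V mouse means: AV/V ratio %.2f, paired t p = %.3g\n",
            mean(per_mouse$av / per_mouse$v), tt$p.value))
write.csv(per_mouse, "results/av_enhancement.csv", row.names = FALSE)

tr1 <- av_trial_responses(sessions[[1]])
mo <- modulation_vs_offset(tr1$responses, tr1$trials)
cat(sprintf("Offset dependence of the AV response (RM ANOVA): p = %.3f\n",
            mo$offset_p))
write.csv(mo$per_offset, "results/av_per_offset.csv", row.names = FALSE)

dec <- decode_offset_from_somata(tr1$responses, tr1$trials,
                                 n_shuffles = 100, seed = 6)
for (cond in c("A", "AV")) {
  d <- dec[[cond]]
  cat(sprintf("%s trials: decoded offset error %.1f deg (shuffle %.1f, chance %.1f)\n",
              cond, d$result$mean_error, mean(d$shuffle_errors), d$chance))
}
cat("Sound boosts visual responses but carries no decodable offset\n")
cat("information in this population, mirroring a gain-like AV interaction.\n")
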