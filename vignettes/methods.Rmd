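---
title: "Quantifying auditory spatial information in cortical axonal populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying auditory spatial information in cortical axonal populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audiospace)
```

## The scientific problem

Primary visual cortex (V1) receives long-range axonal input from auditory
cortex (AC). Two-photon calcium imaging of AC axonal boutons in V1, while
sounds and LED flashes are presented from a grid of positions around the
head, lets one ask whether those inputs carry information about *where* a
sound came from, and whether that information is organized to match V1's
visual retinotopy. `audiospace` implements the full analysis chain for such
experiments — from raw fluorescence traces to population decoding — together
with a synthetic session generator so that every stage can be validated
against a known ground truth without any recorded data.

The stimulus space is a 13 × 3 grid: azimuths −20° (ipsilateral to the
recorded hemisphere) to +100° (contralateral) in 10° steps, elevations −20°,
0°, +20°. A single-elevation rotating-speaker variant covers −90° to +100°
(20° steps up to −30°, then 10° steps). Distances between positions are
Euclidean in the (azimuth, elevation) degree plane, which is exact for the
1-D arm and a close approximation on the small spherical section the array
spans.

## Models and statistics

### Spatial modulation index

For a response map $r_i$ ($i = 1 \dots n$ positions, grand mean $R$):

$$\mathrm{SMI} = \frac{\sum_i^n (r_i - R)^2}{\sum_i^n r_i^2}$$

the fraction of the map's energy not explained by its spatial mean. A
uniform map gives exactly 0. A map confined to a single position gives
$(n-1)/n$ — note this is slightly below 1 (0.974 for $n = 39$); the index is
implemented exactly as defined rather than rescaled to reach 1. Negative
(noise-driven) map entries are admitted as-is; `rectify = TRUE` zeroes them
first (off by default). The *population* SMI is the SMI of the
position-wise mean map across boutons: when tuning centers are spread over
the array, averaging flattens the map and the population SMI falls well
below the mean single-bouton SMI, which is the signature of distributed
(non-aligned) spatial preferences.

### Bouton-to-axon clustering

Boutons of one axon share trial-to-trial activity, so a naive Bayes decoder
that assumes conditional independence must operate on axons, not boutons.
Pairs of ROIs with Pearson correlation ≥ 0.3 are treated as same-axon
pairs; clusters are grown by visiting the qualifying pairs in random order
(a pair joins a cluster when at least one of its ROIs is a member of, or
correlates above threshold with a member of, that cluster; ambiguous pairs
follow their first ROI, and the visiting order is controlled by a seed).
Each cluster's activity is the trial-response row of its largest-mean-dF/F
member. The 0.3 threshold originates from an anatomical calibration
(same-shaft bouton pairs) that cannot be re-derived here and is taken as a
given constant.

### Naive Bayes maximum-likelihood decoder

Training trials give, for each axon $i$ and position $s$, a response mean
$R_{i,s}$ and s.d. $\sigma_{i,s}$ (n−1 denominator). A test trial's
population response $n = (n_1, \dots, n_N)$ is scored per position by

$$\log P(n \mid s) = \sum_i^N \log \mathcal{N}(n_i;\, R_{i,s},\, \sigma_{i,s})$$

and the decoded position $\hat{s}$ is the argmax. The prior $P(s)$ is
uniform and the evidence $P(n)$ is constant in the argmax, so neither is
stored. Decoding error is the Euclidean angular distance between true and
decoded position. Implementation choices that the definition leaves open:

* **Sigma floor** (default $10^{-3}$ dF/F): the normal density is undefined
  at $\sigma = 0$, which occurs whenever a training cell is constant.
* **Stratified folds**: the 5-fold cross-validation assigns trials to folds
  within each position, so every fold trains on every position; each trial
  is decoded exactly once.
* **Ties** in the log-likelihood are broken uniformly at random under a
  recorded seed.
* Sessions are decoded only when clustering yields more than 10 axons; a
  leave-one-out variant serves designs with few repetitions (the
  audiovisual sessions with 7 repetitions per condition).

Chance level is defined by exact enumeration: the mean angular distance
over all ordered position pairs, i.e. the expected error when true and
decoded positions are drawn independently and uniformly from the grid
(50.4° for the default array). The empirical null is a label permutation:
position labels are shuffled across trials and the full cross-validated
decode repeated (100 shuffles by default).

### Tuning reliability and derived summaries

Split-half reliability splits each position's trials randomly in half and
correlates the two half-maps; a bouton is reliable at $r > 0.3$. Within the
100-iteration resampling loops (session best azimuth, distance tuning
curves) the reliable set is re-derived per iteration from a fresh split.
The best azimuth marginalizes over elevation by averaging the map within
each azimuth column; the session statistic is the median across reliable
boutons and requires at least 10 of them. Distance tuning curves take the
preferred position from one random half and normalize the other half's map
to its value at that position, pooling by distance. Azimuth-vs-elevation
modulation is compared on the nine virtual 40° × 40° sub-arrays (azimuth
triplets at 20° spacing crossed with the three elevations) via per-bouton
two-way ANOVA, averaging the significant fractions over sub-arrays — the
full grid's anisotropic sampling (10° vs 20° steps) would otherwise bias
the comparison.

### Receptive fields and the retinotopic-alignment test

The V1 population RF is the baseline-subtracted, repetition- and
neuron-averaged response map over LED positions, fitted with an elliptical
2D Gaussian (amplitude, center, two widths, orientation, offset) by
bounded Levenberg–Marquardt with centroid initialization and jittered
restarts. Orientation and offset are included because empirical maps are
tilted and sit on a pedestal; both are reported. A fit is flagged
unreliable when the amplitude does not exceed four residual standard
deviations (flat maps).

The alignment test regresses session best auditory azimuth on the session's
V1 RF azimuth center (ordinary least squares across sessions), with a
residual bootstrap for the 95% CI of the slope. Complementarily, the
decoding error of single trials is binned by $|$stimulus azimuth − RF
azimuth$|$ in 10° bins, with an optional shuffle-subtracted profile; and
cross-session error-vs-retinotopic-position curves subsample every session
to the same axon count (10 draws, averaged) before a 20°-window, 5°-step
moving average, to remove the population-size confound.

### Audiovisual modulation

The audiovisual protocol fixes a target LED at the population RF center and
places speakers at azimuthal offsets {−40, −20, 0, +20, +40}°; trials are
visual, auditory, or audiovisual, 7 repetitions each. Enhancement is
quantified per neuron as AV − V and AV / V (AV averaged across offsets and
intensities), with a paired t-test across mouse means as the population
statistic. Offset dependence is tested by a repeated-measures ANOVA on
mouse-level condition means (per-neuron fixed effects with the neuron as
the subject when only one session is available); speakers offset in
elevation are excluded. Finally, the speaker offset itself is decoded from
A-only and AV trials with the leave-one-out decoder against a 100-shuffle
null — a gain-like, spatially unspecific interaction predicts chance-level
decoding.

## The synthetic session generator

The generator emulates the statistical structure the analyses assume, with
defaults chosen to match the emulated acquisition: 6 Hz frame rate, 1 s
stimuli with 2 s inter-stimulus gaps, block-randomized interleaved
auditory/visual sequences with 20 repetitions per position, and a
mono-exponential indicator kernel (τ = 1 s for the slow axonal indicator;
the audiovisual somatic sessions use τ = 0.4 s, emulating a faster somatic
indicator).

Per trial, an axon's latent response is its tuning amplitude at the
stimulus position (unnormalized Gaussian falloff in the degree plane;
flat-responsive and non-responsive kinds complete the mixture) times a
shared lognormal trial gain. Each bouton sees the shared latent scaled by a
static lognormal gain plus independent Gaussian noise. The mixing noise is
calibrated in closed form so that the *measured* within-axon
bouton–bouton correlation of trial responses matches the target
`within_axon_corr`: because the indicator kernel attenuates window means
(factor computable exactly from τ, the frame rate and the window; see
`kernel_attenuation()`) and the white trace noise adds variance
$\sigma_\eta^2(1/W + 1/B)$ for $W$ response and $B$ baseline frames, the
calibration solves
$\rho = \alpha^2 v / (\alpha^2 (v + \sigma_\varepsilon^2) + n_0)$
for $\sigma_\varepsilon^2$ given the realized latent variance $v$. When the
target is unattainable at the session's signal-to-noise ratio the mixing
noise clamps at zero. Signals are rendered as boxcars over the stimulus
frames, convolved with the normalized kernel, and white noise is added on
a baseline of 1 so that dF/F equals the signal; the pre-kernel boxcar trace
is emitted as the deconvolved-event channel (deconvolving the noise-free
fluorescence recovers it exactly).

Numbers worth knowing (defaults; all overridable):

| parameter | default | meaning |
|---|---|---|
| `frame_rate` | 6 Hz | volumetric scan rate |
| `stim_duration` / `isi` | 1 s / 2 s | stimulus and gap |
| `indicator_tau` | 1 s | indicator decay |
| `noise_sd` | 0.1 dF/F | white trace noise |
| `trial_gain_sd` | 0.25 (log-sd) | shared trial gain variability |
| `within_axon_corr` | 0.6 | bouton–bouton response correlation target |
| responsiveness | α = 0.01, amp > 0.15 dF/F | Wilcoxon + amplitude gates |
| reliability / clustering r | 0.3 | split-half and pair thresholds |
| decoder | 5 folds, floor 10⁻³, > 10 axons | cross-validation settings |

What the generator does *not* emulate: imaging-plane structure (pixels,
neuropil contamination beyond a constant-fraction channel, motion),
correlated noise across axons, adaptation or history effects, and
behavioral covariates (pupil, face motion). Passing tests therefore show
the analysis chain is correct and calibrated under the stated statistical
assumptions — not that those assumptions exhaust real recordings.

## Design choices in ambiguous corners

* **Trial baseline**: fixed as the 1 s immediately preceding onset
  everywhere; F0 is its mean, and dF/F windows are half-open `[start, end)`
  with the onset frame the first frame whose start time is at or after the
  stimulus onset.
* **Wilcoxon pairing**: per-trial response-window mean vs baseline-window
  mean of the same trial (the baseline equals the F0 window, so the paired
  test reduces to a one-sample test of the response); zero differences are
  dropped, the standard convention. Note the paired signed-rank test needs
  at least 10 repetitions to be able to reject at α = 0.01 under the
  normal approximation — designs with fewer repetitions gate nothing.
* **Amplitude gate statistic**: the mean response at the best position
  (a `median` switch is provided; the defining text does not say which).
* **Clustering signal**: correlations are computed on whatever ROI × time
  matrix is supplied — full concatenated dF/F traces in the pipeline, or
  trial responses where trace-level correlations are too diluted by
  between-trial frames; the within-axon correlation target refers to trial
  responses, so benchmarks cluster those.
* **Resampling unit for the session best azimuth**: the random split-half
  (trial level), re-qualifying reliable boutons per iteration; the bouton's
  best azimuth itself comes from all trials.
* **Motorized-arm trial count**: the enumerated step plan gives 17
  positions; the generator parameterizes repetitions and never hard-codes a
  session's total trial count.
* **Virtual-array construction**: azimuth index triplets (i, i+2, i+4),
  giving |azimuths| − 4 = 9 sub-arrays on the default grid.

## Problem sizes used by the test-suite benchmarks

The packaged tests validate each property at sizes chosen to make the
check statistically decisive while staying quick on a laptop: clustering
recovery uses 20 axons × 3 boutons over 780 trials (distinct centers,
trial-gain log-sd 1 — high shared-gain variability is what keeps cross-axon
correlations near zero while within-axon correlations hit 0.6); decoder
recovery uses 50 width-30° axons at amplitude/noise 3 with 20 repetitions;
the retinotopy null uses 20 replicates of 40 sessions with 20 boutons
each; the audiovisual replication uses 30 sessions of 25 neurons. The
qualitative audiovisual findings are scored at α = 0.01 (enhancement
present, offset effect absent, decoding within three shuffle s.d. of the
null mean), chosen a priori as the replication criterion for a
*qualitative* finding.

## Known limitations

* The sequential clustering rule is order-dependent by construction; the
  seed pins the order, and seed-to-seed agreement is itself tested
  (adjusted Rand index > 0.95 on the benchmark).
* The decoder's Gaussian observation model is used as defined even though
  dF/F responses are skewed; no Poisson or kernel-density variant is
  provided.
* `chance_error()` assumes a uniform decoded-position distribution; a
  decoder with degenerate likelihoods can sit slightly off that value
  while still being "at chance" relative to its own shuffle null, which is
  why both references are reported.
* Azimuth preference marginalizes elevation by averaging; boutons tuned to
  extreme elevations have attenuated azimuth marginals and correspondingly
  noisier best-azimuth estimates.
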