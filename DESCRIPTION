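Package: audiospace
Title: Auditory Spatial Information in Cortical Axonal Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying auditory spatial information in
    two-photon calcium-imaging recordings of axonal boutons and cortical
    somata. Provides stimulus-array geometries, a synthetic session generator
    with known ground truth, trial segmentation and responsiveness filters,
    the spatial modulation index, split-half tuning reliability, best-azimuth
    and distance-tuning summaries, correlation-based clustering of boutons
    into putative axons, a naive Bayes maximum-likelihood decoder of stimulus
    position with cross-validation and shuffle nulls, 2D Gaussian population
    receptive-field fitting with a retinotopic-alignment test, and
    audiovisual modulation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
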