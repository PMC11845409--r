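Package: stridesync
Title: Gait-Cycle Entrainment Analysis of Saccades and Mobile EEG
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis pipeline for mobile eye-tracking and EEG
    recorded during walking. Detects saccades from head-fixed gaze streams
    with a 2D velocity-threshold algorithm, extracts step and stride phase
    from vertical head position, tests for oscillations of saccade
    likelihood across the stride cycle with forced-frequency Fourier fits
    and permutation nulls, estimates Bayesian population prevalence of
    within-participant effects, computes gait- and saccade-locked Morlet
    time-frequency power, and performs cluster-based permutation inference
    on time-frequency and topographic maps. Includes a synthetic-session
    generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
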