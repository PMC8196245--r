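Package: alphanorm
Title: Normative Modelling of Eyes-Closed Alpha-Rhythm Power in Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for empirical-CDF normative modelling of
    alpha-band spectral power in routine scalp EEG. Recordings are band-pass
    filtered, reduced to an eight-channel bipolar montage, cut into z-scored
    10-second eyes-closed windows, and summarised by sixteen log-transformed
    alpha-power fractions (eight channels by two alpha sub-bands) estimated with
    multitaper spectral estimation. Per-feature empirical cumulative
    distribution functions fitted on a healthy reference population turn new
    windows into probability-of-normality scores, which are aggregated to
    subject level and evaluated with repeated train/test splits, ROC analysis
    with convex-hull threshold selection, Wasserstein-distance group contrasts,
    rank-sum tests and Tukey honestly-significant-difference comparisons. A
    synthetic-cohort generator with controllable alpha-power structure (1/f
    background, posteriorly dominant alpha, eyes-closed amplification, group
    and hemisphere effects, eye-blink artefacts) makes every stage testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
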