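Package: classqs
Title: Cluster-Based Adaptive Sleep Staging for Preterm Neonatal EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated detection of quiet sleep (QS) in multichannel EEG
    recordings of preterm neonates over a wide postmenstrual age range.
    Implements the CLASS algorithm (CLuster-based Adaptive Sleep Staging):
    artifact subspace reconstruction (ASR) with robust geometric-median
    calibration, adaptive nonstationary segmentation, k-means cluster-time
    profiles, and envelope thresholding with a minimum-duration rule.
    Ships an NLEO/SAT% baseline detector, sample- and event-level agreement
    metrics (sensitivity, specificity, detection and misclassification
    factors, ROC/AUC, Cohen's kappa), quiet-sleep-specific brain-maturation
    features with mixed-model trend regression, and a synthetic preterm-EEG
    simulator with ground-truth hypnograms for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    sandwich,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
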