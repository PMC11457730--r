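Package: coopeeg
Title: Neurophysiological Cooperation Metrics for Dyadic EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cooperation between two operators from wearable EEG
    without requiring hyperscanning. Implements the circular-correlation
    cooperation index (CCI) on instantaneous EEG phases and the
    mutual-information cooperation index (MICI) on EEG-derived mental-workload
    and approach-withdrawal feature series, estimated with a from-scratch
    Kraskov-Stoegbauer-Grassberger k-nearest-neighbour mutual-information
    estimator. Includes the full preprocessing chain (band-pass and notch
    filtering, 1-s epoching, amplitude artifact masking, channel exclusion),
    individual-alpha-frequency anchored band definitions, global field power
    features, calibration-median cooperation thresholds and cooperation-time
    percentages, surrogate (FAKE) crew construction, normality-gated group
    comparisons, and a synthetic dyadic-EEG simulator with known ground-truth
    phase coupling and cognitive-state structure so the whole pipeline is
    verifiable without real recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
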