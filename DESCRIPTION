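Package: fewt
Title: Fuzzy-Refined Empirical Wavelet Features for EEG Mental-Task
    Classification
Version: 0.1.0
Authors@R:
    person("FEWT", "Maintainers", email = "fewt@example.org", role = c("aut", "cre"))
Description: Adaptive empirical wavelet transform (EWT) feature extraction
    for multi-channel EEG, with fuzzy c-means refinement of overlapping
    wavelet supports into non-overlapping frequency bands (FEWT), an
    eight-parameter statistical band descriptor set, three multivariate
    filter feature-selection criteria (Bhattacharyya distance, scatter-matrix
    trace ratio, linear-regression R-squared), a cross-validated
    Gaussian-kernel classification harness, percentage-gain ranking of
    method combinations, and a Friedman rank comparison.  Includes
    synthetic AM-FM and EEG-like trial generators so the full pipeline is
    testable without external recordings, plus a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
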