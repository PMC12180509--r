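Package: zeitshift
Title: Circadian Phase-Shift Quantification for Locomotor and Calcium Rhythms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify stimulus-induced phase shifts of the circadian
    pacemaker from wheel-running actograms (activity-onset detection, onset
    regression, chi-square periodogram), from event-locked fiber photometry
    (isosbestic-corrected dF/F, trial segmentation, AUC/peak/latency metrics,
    SD-threshold response classification), from duty-cycled long-term
    photometry (session-level calcium rhythm extraction, per-cycle cosinor
    acrophase, acrophase-based phase shifts), and from two-photon ROI trace
    matrices (evoked response typing). Includes a synthetic-data generator
    that emulates each recording modality with known ground truth so every
    estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
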