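Package: onseterp
Title: Onset-Paradigm Difference-ERP Analysis for Bistable Perception EEG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing stimulus-locked EEG from Onset-Paradigm
    experiments on bistable perception. Computes reversal-minus-stability
    difference event-related potentials (dERPs), tests for the presence of
    reversal-related components (Reversal Positivity, Reversal Negativity,
    Parietal/Frontopolar Positivity, Frontal Negativity) with running
    t-tests and run-length criteria, measures ROI peak amplitudes and
    latencies with a fallback averaging rule, and runs mixed-design ANOVAs
    with partial eta squared plus Wilcoxon post-hocs under Bonferroni-Holm
    correction. Ships a synthetic cohort generator with planted components,
    a BrainVision reader/writer, and a generic source-cluster stage
    (per-vertex t-tests, thresholding, repeated k-means with elbow
    selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
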