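Package: liftload
Title: Personalized EMG-Driven Estimation of Low-Back Loading and NIOSH Lifting Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing low-back loading during manual lifting.
    Implements the Revised NIOSH Lifting Equation (recommended weight limit,
    lifting index, risk bands, and inverse task design for a target lifting
    index), surface-EMG and kinematics conditioning (zero-phase Butterworth
    filtering, velocity-threshold lift-cycle segmentation, iMVC-normalized
    envelopes, 201-point time normalization), a planar EMG-driven trunk model
    with lumped Hill-type muscle-tendon units that estimates sagittal
    lumbosacral moments and L5-S1 compressive and shear loads, per-subject
    calibration of muscle-tendon parameters against inverse-dynamics moments,
    a seeded synthetic lifting-trial generator emulating three risk
    conditions, and risk statistics including Wilcoxon comparisons across
    risk levels and centroid clustering of compressive loads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
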