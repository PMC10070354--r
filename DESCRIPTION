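Package: gstopo
Title: Global Signal Topography of the Self and Emotion-Severity Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how strongly individual brain regions represent
    global fMRI activity (Fisher-z global signal correlation, GSCORR) within the
    three-layer topography of self (interoceptive, exteroceptive, mental), and to
    link that representation to trial-level emotion-severity ratings. Includes
    temporal preprocessing variants (infra-slow band-pass or high-pass, with and
    without global signal regression), sphere-based MNI ROI machinery, parcelwise
    group comparison with a resampling positive-FDR procedure, Wilcoxon/ANCOVA
    group statistics, chi-square analyses of behavioural responses with
    standardized Pearson residuals, and per-condition multinomial logistic
    regression with relative risk ratios and repeated cross-validation. A
    synthetic-data module generates BOLD-like volumes with a controllable shared
    global component and behavioural responses from a known multinomial model so
    that every stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
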