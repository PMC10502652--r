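Package: miFCswitch
Title: Mutual-Information Functional Connectivity Under Switching Predictability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-validated pipeline for studying how the
    predictability of task switching shapes brain functional connectivity.
    Generates fully factorial 2x2x2 switching task designs (sequential,
    perceptual and spatial predictability), simulates BOLD timeseries with
    known linear and nonlinear regional coupling, parcellates 3D statistical
    maps by a rank-ordered watershed, estimates pairwise mutual-information
    functional connectivity (miFC) with a leave-one-out Gaussian kernel
    density estimator, screens reliability with intraclass correlations,
    tests per-edge factorial predictability effects with a repeated-measures
    ANOVA and Benjamini-Hochberg FDR control, and summarises significant
    edges as weighted network graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    lme4,
    lmerTest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
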