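Package: marrowtex
Title: Radiomic Texture Analysis of Bone-Marrow MRI Regions of Interest
Version: 0.1.0
Authors@R: person("Marrowtex", "Developers", role = c("aut", "cre"),
    email = "maintainer@marrowtex.org")
Description: An 81-descriptor radiomic texture engine for 2D masked
    bone-marrow MRI regions of interest (first-order statistics, gray-level
    co-occurrence, run-length and size-zone matrices, Tamura and local
    binary pattern descriptors), a three-group statistical comparison
    workflow (Jarque-Bera normality branching into ANOVA or Kruskal-Wallis,
    Benjamini-Hochberg false discovery rate control, Tukey/Dunn post hoc
    pairwise tests), and a combinatorial feature-selection and
    classification protocol (random-forest importance ranking, exhaustive
    small feature combinations, class balancing with bootstrap resampling
    and SMOTE, repeated stratified split plus cross-validated evaluation).
    Includes a calibrated synthetic cohort generator emulating three
    diagnostic groups in two MRI sequence channels so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
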