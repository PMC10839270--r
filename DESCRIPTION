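Package: salivaMS
Title: Spatially and Temporally Resolved Salivary Metabolomics
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for semi-targeted LC-MS/MS salivary metabolomics with a
    spatial (oral location) by temporal (time of day) sampling design.
    Provides a SummarizedExperiment-based feature-table container with
    readers and writers, a synthetic cohort and feature-table simulator
    with plantable location, diurnal and correlation effects, construction
    of an authentic-standard consensus MS/MS spectral library with MSP
    import/export, exact-mass/RT/MS2 identification at MSI confidence
    levels 1 and 3, feature-table curation (blank filtering, QC-pool RSD
    filtering, adduct summation, dual-polarity merging) with provenance
    accounting, the stratified spatial-temporal statistical battery
    (pairwise Wilcoxon rank-sum tests with Bonferroni correction and fold
    changes, Spearman correlation networks, Ward2 hierarchical clustering,
    subset PCA), and partial least squares discriminant analysis with VIP
    scoring, cross-validated R2Y/Q2 and permutation validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
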