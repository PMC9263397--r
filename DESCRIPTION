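Package: gfcmap
Title: Voxel-Wise Global Functional Connectivity Mapping and Group Inference
    for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxel-wise global functional connectivity (GFC) maps --
    the per-voxel mean Fisher-z-transformed Pearson correlation with every
    other gray-matter voxel -- from 4D BOLD volumes, and carries them through
    a complete group-analysis pipeline: volume discard, linear detrending,
    temporal band-pass filtering, Friston-24 plus compartment nuisance
    regression, head-motion quality control with frame-wise displacement,
    mass-univariate three-group ANCOVA with Benjamini-Hochberg FDR
    correction, post hoc covariate-adjusted t contrasts with 3D cluster
    extraction and peak reporting, summary-statistics reconstruction of
    demographic and clinical test statistics, BH-corrected clinical
    correlations, and leave-one-out support-vector-machine classification of
    clinical groups from cluster-mean features.  Includes a deterministic
    synthetic three-group cohort generator with planted connectivity effects
    so that every stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    e1071,
    igraph,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    signal,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
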