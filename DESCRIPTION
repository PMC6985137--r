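Package: fcdstrat
Title: Functional Connectivity Density Stratification for Premanifest Huntington's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-level functional connectivity density (FCD) analysis for
    stratifying premanifest Huntington's disease carriers by their rate of
    longitudinal cognitive and motor decline from a single resting-state fMRI
    visit. Provides BOLD preprocessing (frame trimming, tCompCor nuisance
    removal, zero-phase band-pass filtering, motion quality control), FCD map
    construction (thresholded correlation degree, log transform, median
    normalization, masked Gaussian smoothing), longitudinal decline slopes with
    control-based age and sex correction, robust principal components via the
    minimum covariance determinant, elastic-net logistic stratifiers validated
    with leave-one-site-out cross-validation, connectome-fingerprinting
    test-retest reliability, confound controls (ComBat site harmonization,
    grey-matter-concentration residualization, control-learned motion
    detrending), nonparametric voxelwise statistics with false discovery rate
    control, and a seeded synthetic multi-site cohort generator that emulates
    the data structure of a premanifest HD imaging study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    signal,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    sva,
    pROC
Config/testthat/edition: 3
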