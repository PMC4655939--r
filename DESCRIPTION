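Package: rsfcrepro
Title: Reproducibility Analysis of Dual-Regression Resting-State fMRI Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-group resting-state fMRI cohorts with known spatial
    networks, structured artefacts and a planted basal-ganglia connectivity
    deficit, and runs the full group-comparison pipeline on them: ICA-based
    nuisance regression (soft and aggressive variants), group-ICA template
    construction with temporal concatenation, dual regression, ROI t-tests
    with Bonferroni correction, and voxel-wise Freedman-Lane permutation
    inference with threshold-free cluster enhancement (TFCE). Includes
    temporal-SNR, spatial-correlation and Dice reproducibility metrics for
    comparing pipeline variants and split-half cohort analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    ica,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    clue,
    jsonlite,
    withr
Config/testthat/edition: 3
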