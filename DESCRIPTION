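Package: tremornet
Title: Voxel-Wise Centrality and Weighted Network Efficiency Analysis of
    Resting-State fMRI Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for resting-state BOLD fMRI discoordination
    analysis in two-group (patient versus control) designs: temporal
    preprocessing (volume dropping, detrending, ideal band-pass filtering,
    Friston-24 plus white-matter/cerebrospinal-fluid nuisance regression,
    head-motion summaries), voxel-wise weighted degree centrality with
    Bonferroni-thresholded positive correlations, sphere-ROI seed-based
    functional connectivity with Fisher r-to-z maps, sparsity-swept weighted
    network global and local efficiency with degree-preserving
    (Maslov-Sneppen) null-model normalization and small-world assessment,
    group statistics (covariate-adjusted GLM t-maps with Monte-Carlo
    cluster-extent correction, Freedman-Lane permutation tests,
    Benjamini-Hochberg correction across sparsities, partial Spearman
    brain-behavior correlation) and ROC discrimination. A synthetic
    two-group BOLD cohort generator with planted region covariance, hub
    voxels and clinical-score coupling provides ground truth for every
    stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    withr
Config/testthat/edition: 3
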