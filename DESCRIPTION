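Package: radrobust
Title: Robustness of Radiomic Feature Quantification Under Segmentation
    Variability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation framework for studying how tumor segmentation
    variability propagates into radiomic features. Generates synthetic 3D
    CT-like tumor phantoms with simulated manual delineations and
    semi-automatic GrowCut segmentations, extracts a 56-feature radiomic
    panel (15 first-order intensity, 8 shape, 33 texture features from
    gray-level co-occurrence and run-length matrices), and quantifies
    inter- and intra-observer reproducibility with intraclass correlation
    coefficients (one-way and two-way mixed absolute-agreement ANOVA
    estimators), reproducibility classes, Wilcoxon rank-sum comparisons,
    and Z-score normalized feature-range analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
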