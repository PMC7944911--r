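Package: gliosom
Title: Voxel-Wise Two-Level Clustering of Multiparametric MR/PET for Glioma
    Genotype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a voxel-wise unsupervised two-level clustering pipeline
    (batch self-organizing map followed by K-means over protocluster weight
    vectors) for co-registered multiparametric MRI and amino-acid PET brain
    tumor volumes, together with the downstream genotype classifier it feeds:
    per-subject tumor label-fraction log-ratio features, a linear support
    vector machine evaluated by leave-one-out cross-validation with a nested
    two-step grid search for the cost parameter, bootstrap comparison of
    classifier performance across cluster numbers (one-way ANOVA with Tukey
    HSD), and per-label Mann-Whitney U tests with Benjamini-Hochberg
    correction. Ships a synthetic multiparametric cohort generator so the
    whole pipeline is reproducible and testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ggplot2,
    withr
Config/testthat/edition: 3
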