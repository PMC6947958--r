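Package: episignr
Title: Discovery and Classification of Blood DNA-Methylation Episignatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for deriving syndrome-specific DNA methylation
    "episignatures" from Illumina 450K/EPIC beta-value matrices and turning
    them into a confidence-scored classifier. Covers probe- and array-level
    quality control (detection p-values, sex-chromosome/SNP/cross-reactive
    probe removal, sex prediction, bimodality and PCA outlier checks),
    iterative age- and sex-matched control selection, reference-based
    leukocyte deconvolution by constrained projection, cell-composition-
    adjusted moderated linear modelling of M-values with empirical-Bayes
    variance shrinkage and Benjamini-Hochberg correction, kernel-smoothed
    differentially methylated region calling with Stouffer-combined FDR,
    hierarchical clustering and classical multidimensional scaling
    diagnostics, and a random-forest classifier reporting tree-vote
    confidence scores. A synthetic cohort generator with known ground truth
    makes every stage testable without access to patient arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    quadprog,
    randomForest,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
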