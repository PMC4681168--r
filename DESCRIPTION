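Package: gvhdmeth
Title: Donor DNA Methylation Classification of Acute Graft-Versus-Host
    Disease Severity
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for donor-specific DNA
    methylation classifiers of acute graft-versus-host disease (aGVHD)
    severity after hematopoietic stem cell transplantation. Covers
    beta-value computation and probe-level quality filtering for Illumina
    450K-style methylation matrices, empirical-Bayes (ComBat-style) batch
    adjustment, reference-based leukocyte deconvolution, covariate-adjusted
    differential methylation with moderated t-statistics, probe-lasso
    differentially methylated region calling, nearest-shrunken-centroid
    classification under nested leave-one-out cross-validation with
    ROC/AUC evaluation, and MethyLight percent-methylated-reference (PMR)
    quantification from qPCR plates. A synthetic-data module generates
    cohorts and plates with known ground truth so every stage is
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
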