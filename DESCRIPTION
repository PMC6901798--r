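Package: methpanel
Title: Discovery and Validation of DNA Methylation Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for discovering compact DNA methylation biomarker panels that
    separate tumor from normal tissue on Illumina-style beta-value arrays.
    Implements beta/M-value transforms, gene-wise batch mean-centering across
    cohorts, empirical-Bayes moderated t-statistics for differential methylation
    calling, exact one-dimensional two-means binarization of probe values,
    random-forest recursive feature elimination with a greedy correlation-filtered
    panel build scored by stratified cross-validated accuracy and Cohen's kappa,
    and imbalance-corrected external validation using smoothed-bootstrap (ROSE
    style) minority oversampling. Includes a seeded synthetic-cohort generator
    that emulates the statistical structure of tumor/normal methylation arrays so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
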