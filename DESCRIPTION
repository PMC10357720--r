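Package: puvote
Title: Positive-Unlabeled Bagged SVM Ensembles for Pathway Gene
    Discovery in Cancer Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies genes co-patterned with a seed pathway gene set
    (e.g. the TNFA-signaling-via-NFkB hallmark) across cancer cohort
    transcriptomes by positive-unlabeled (PU) learning: bagged linear
    support vector machine member classifiers are trained with genes as
    samples and patients as features, and majority voting over members
    scores every gene in the transcriptome.  Includes negative-to-positive
    sampling-ratio calibration, pan-cancer vote aggregation, a Pearson
    correlation baseline, permutation-based gene set enrichment (GSEA)
    statistics, Jaccard functional similarity over annotation terms,
    protein-protein interaction functional-module discovery with
    module-activity and module-classifier analyses, risk scoring with
    Kaplan-Meier stratification, and a self-contained synthetic-data
    generator that plants the statistical structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    survival,
    utils,
    graphics,
    yaml
Suggests:
    fgsea,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
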