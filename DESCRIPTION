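Package: proteorestore
Title: Quantifying Therapy-Induced Reversal of Disease Proteome Remodeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of label-free quantitative proteomics for
    three-cohort intervention designs (control, disease, disease plus
    therapy). Provides total-ion-current normalization and log2
    transformation of protein intensity matrices, per-protein pairwise
    cohort contrasts with fold-change and p-value gates, a
    full/partial/none reversal taxonomy for disease-altered proteins,
    functional-category impact and remediation scoring, hypergeometric
    annotation enrichment with Benjamini-Hochberg correction, upstream
    regulator activation z-scores over user-supplied signed networks,
    proteome state-space displacement via PCA and squared Euclidean
    distances, and a synthetic cohort simulator with planted ground truth
    for parameter-recovery validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
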