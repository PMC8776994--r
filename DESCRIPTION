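Package: m6aTME
Title: m6A-Regulator Subtyping and Scoring of the Tumor Microenvironment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for N6-methyladenosine (m6A) regulator
    analysis of tumor transcriptomes: empirical-Bayes moderated differential
    expression, single-sample gene-set enrichment (ssGSEA) immune-infiltration
    scoring, nonnegative matrix factorization (NMF) consensus subtyping with
    silhouette- and survival-guided model selection, univariate Cox screening
    of prognostic genes, a PCA-based m6A score with optimal-cutpoint survival
    stratification, and a Spearman-based mRNA stemness index. Ships a
    curated 26-gene m6A writer/reader/eraser registry and a synthetic cohort
    generator that emulates the statistical structure of a nasopharyngeal
    carcinoma expression cohort with progression-free survival, so every
    stage is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    cluster,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
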