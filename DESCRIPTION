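Package: oncoverge
Title: Integrative Multi-Omics Convergence Analysis for Small Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-level integration of copy-number, expression, point-mutation
    and fusion evidence for small cancer cohorts where recurrence statistics
    lack power. Classifies copy-number segments as focal or arm-level,
    annotates genes onto focal segments, bins expression by percentile rank of
    log10(FPKM + 1), filters variants by coverage, germline-catalog
    subtraction, functional-prediction voting and exome/transcriptome
    cross-validation, and prioritizes genes altered by two or more mechanisms
    within or across samples. Also computes cohort-level cumulative alteration
    frequency (oncoprint-style sample-set unions) and a three-class gene
    typology. Ships a synthetic-cohort simulator with planted ground truth so
    every filtering stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
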