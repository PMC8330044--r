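Package: wtsALL
Title: Stepwise Whole-Transcriptome Classification of Acute Lymphoblastic Leukemia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a stepwise classifier for acute lymphoblastic leukemia
    (ALL) from whole-transcriptome sequencing: sample-pairing quality control by
    SNP allele concordance between RNA and DNA assays, TMM-normalized log2 CPM
    expression with marker-based lineage assignment, consensus fusion-transcript
    calling with WGS confirmation and control filtering, expression-derived
    chromosome-level copy-number states with rule-based ploidy-group calls, and
    a median-profile Euclidean-distance BCR-ABL1-like (Ph-like) classifier.
    Ships a synthetic cohort generator with planted truth labels so the whole
    pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    edgeR,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Classification, CopyNumberVariation
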