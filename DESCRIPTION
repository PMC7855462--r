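Package: gfblup
Title: Genomic-Feature Mixed Models for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction in inbred plant panels with genomic-feature
    mixed models. Implements GBLUP, two-component GFBLUP (a genomic feature
    defined by a gene set plus the remaining genome) and adaptive MultiBLUP
    with an average-information REML solver, VanRaden genomic relationship
    matrices, marker quality control (missing-call removal, minor-allele
    frequency filtering, windowed LD pruning), design-adjusted phenotypes
    (best linear unbiased estimators from a replicated field/imaging design),
    mapping of Gene Ontology terms, co-expression clusters and curated gene
    lists to marker sets via gene coordinates, repeated k-fold
    cross-validation with shared splits, likelihood-ratio tests against the
    point-mass/chi-squared boundary null, and a genome-wide feature scan with
    Benjamini-Hochberg control. A synthetic-data generator reproduces the
    statistical structure of a homozygous diversity panel so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    lme4,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
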