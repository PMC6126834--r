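Package: stratenrich
Title: Stratified Enrichment of GWAS Associations in Functional Variant Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies excess of trait associations among annotated variant
    sets (tissue eQTLs, chromatin-state categories, proximal and distal
    regulatory variants) relative to matched control variants, from GWAS
    summary statistics. Implements random LD-based pruning replicates,
    intergenic genomic control by median of medians, stratified Q-Q and
    conditional fold-enrichment (CDF-ratio) curves, chi-squared general
    linear models with annotation covariates and interaction terms
    meta-analysed across pruning replicates, Storey-type estimation of the
    proportion of non-null associations, Mann-Whitney comparisons,
    matched-control selection on minor allele frequency and distance to
    transcription start site, and an LD-window locus-overlap enrichment
    test. Ships a synthetic-data generator producing block-LD variant maps,
    tissue-tagged annotation sets and summary statistics with
    annotation-dependent non-null structure, so the whole pipeline runs and
    is validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
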