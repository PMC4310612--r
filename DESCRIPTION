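Package: TissueQTL
Title: Multi-Tissue Mapping of Genetic and Epigenetic Effects on
    Expression, Methylation and Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for cis mapping of molecular quantitative trait loci
    across several cell types of the same individuals. Implements
    Spearman rank-correlation scans for expression, DNA methylation and
    alternative-splicing phenotypes with two permutation-based
    multiple-testing schemes (a fixed 1000-round gene-level scheme and
    an adaptive empirical p-value scheme followed by Storey q-values),
    paired-read exon-exon link quantification of relative splicing with
    insert-size-aware link coverage, allele-specific expression testing
    with reference-bias-corrected exact binomial tests and a weighted
    allelic-ratio distance between samples, scaled effect sizes and
    cross-tissue sharing statistics (pi1, effect-size R-squared, sign
    concordance), matched-null genomic feature enrichment, and a seeded
    synthetic cohort generator with a queryable planted-effect registry
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
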