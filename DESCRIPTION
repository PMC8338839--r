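Package: pleioselect
Title: Pleiotropy Degree, Effect Sizes and Background Selection in
    Trait-Associated Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies trait-associated variants from GWAS-Catalog-style
    association tables by their degree of pleiotropy (the number of distinct
    traits a locus is associated with), converts odds-ratio effects to the
    liability scale through the threshold model, computes per-locus
    heritability contributions h2 = 2 beta^2 q (1 - q), annotates loci with
    background-selection (B statistic) and recombination-rate genomic tracks,
    and relates the degree of pleiotropy to effect size, minor allele
    frequency, heritability and the strength of background selection using
    simple and partial least-squares regression.  Ships a seeded
    synthetic-data generator with planted parameters and a machine-readable
    truth file so that every pipeline stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
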