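Package: crmdetect
Title: Training-Data-Free Detection of Cis-Regulatory Modules from Motif Density
Version: 0.1.0
Authors@R:
    person("Regulatory", "Genomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects cis-regulatory modules (CRMs) in genomic sequence without
    any training data. Sequences are scanned on both strands with a position
    weight matrix (PWM) library using log-odds scores and exact
    score-distribution cutoffs; per-position binding-site density is converted
    to chromosome-wise Z-scores; CRMs are called by thresholded seeding with
    gap-limited extension to zero-crossing boundaries. The package also builds
    length-matched predicted-non-functional control regions, evaluates
    predictions against experimentally defined regulatory regions (overlap
    sensitivity, odds ratios, chi-square tests, positional-shuffle nulls),
    consolidates redundant motifs by ALLR similarity, performs hypergeometric
    gene-set enrichment, exports CRM-by-TF binding-site abundance matrices,
    and generates synthetic genomes with implanted motif clusters for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
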