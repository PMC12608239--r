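Package: recmap
Title: Pooled-Sequencing Mapping of a Recessive Locus with IBD Screening and
    Expression-Based Candidate Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing a fully penetrant recessive mutation from
    bulked-segregant pooled whole-genome sequencing of F2 crosses. Implements
    Mendelian expectations and segregation tests for het x het crosses,
    per-site and sliding-window pooled F_ST scans with genome-wide
    Z-standardization and candidate-region calling, segregation-pattern
    variant filtering on allele-frequency differences between phenotype
    pools, identity-by-descent screening of outside individuals via
    per-region genetic distances, coding-consequence annotation on gene
    models (including truncated-protein lengths for stopgains), and
    negative-binomial differential-expression calling with hypergeometric
    over-representation and candidate-gene prioritization. A seeded
    synthetic-data generator emulates the full experimental design (two
    het x het crosses segregating a recessive causal SNP, phenotype pools,
    low-coverage outside individuals from multiple farms, toy gene models
    and a 3 vs 3 expression matrix) so the whole pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    IRanges
Config/testthat/edition: 3
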