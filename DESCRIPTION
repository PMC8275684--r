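Package: hmctools
Title: Spike-In Calibrated 5-Hydroxymethylcytosine Site Calling and
    Tissue-Specific Differential Region Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of base-resolution hydroxymethylomes
    produced by bisulfite-free C-to-T conversion chemistry. Estimates
    conversion rates from spike-in controls, calls single-base 5hmC sites
    with an exact binomial test under Holm family-wise error control and
    peak gating, classifies cytosine sequence contexts and CpG strand
    symmetry, builds merged-peak count matrices with median-of-ratios
    normalization, detects tissue-specific differentially
    hydroxymethylated regions with a one-tailed Poisson test and
    Bonferroni correction, links regions to putative target genes by
    windowed Pearson correlation of region signal with expression, and
    tests SNP-catalog enrichment with one-sided Fisher's exact tests. A
    fully seeded synthetic-data generator with planted truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    withr,
    yaml,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
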