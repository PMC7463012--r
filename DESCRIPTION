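Package: tumorpool
Title: Sampling-Strategy Analysis for Multi-Region Tumor Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how tumor sampling strategy (single biopsy,
    combined local biopsies, pooled multi-region samples) affects somatic
    mutation detection in high-coverage exome sequencing. Implements a
    Poisson background-noise joint genotyper for rescuing candidate somatic
    genotypes across samples of one patient, purity-corrected variant allele
    frequency filters, trunk/branch/private and clonal/sub-clonal mutation
    classification, loss-of-heterozygosity detection at germline heterozygous
    sites inside B-allele-loss segments via Fisher's exact test, and an in
    silico read-pooling experiment (composition and coverage sweeps via
    binomial/hypergeometric count thinning and bootstrap upscaling). A
    synthetic multi-region tumor generator with known clonal ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
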