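Package: haploscan
Title: Genome-Wide Haplotype-Based Association Analysis with Sliding
    Centimorgan Windows and Mixed Linear Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for genome-wide haplotype-based association
    studies of binary traits in family-structured cohorts.  Phased
    genotypes are partitioned into overlapping sliding windows of fixed
    genetic-map length (1, 0.5 and 0.25 cM); distinct haplotype alleles
    within each window are catalogued, frequency- and Hardy-Weinberg
    filtered, and tested for association under a mixed linear model with
    one or two SNP-based genomic relationship matrices fitted by AI-REML.
    Includes fine mapping of overlapping associated haplotype boundaries,
    LD-clump-based multiple-testing correction, genomic-control
    diagnostics, fixed-effect inverse-variance meta-analysis, an allelic
    replication power calculator, and a pedigree-aware synthetic cohort
    simulator with planted causal haplotypes under a liability-threshold
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
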