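Package: PoolSexScan
Title: Sex-Linked SNP, Shared-Polymorphism and CNV Analysis for Pooled Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sex-patterned SNPs from male/female pooled whole-genome
    sequencing of XY (or WZ) systems and characterises candidate
    sex-determination regions. Computes per-site differentiation statistics
    (FST, dxy, da, Nei's D and the Cp half-L1 distance), calls 10 kb windows
    enriched for sex-patterned SNPs, compares region densities with
    Mann-Whitney U tests under Bonferroni control, intersects sex-patterned
    SNPs between species with X/Y-allele consistency classes and a null
    expectation for the shared count, merges conserved copy-number variants
    across VarScan-style comparisons, and scans allele-specific flanking
    sequence against JASPAR position frequency matrices for binding sites
    gained or lost between X and Y alleles. A synthetic-data module simulates
    pooled binomial read sampling from an XY cross with known truth so the
    whole pipeline is testable offline.
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
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
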