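Package: rsbscan
Title: Cross-Population Selection Scans with the Rsb Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects footprints of recent positive selection by contrasting
    extended haplotype homozygosity between a selected and a reference
    population. Implements site-specific EHH (EHHS) decay profiles, their
    physical-distance integral (iES), the standardized cross-population
    log-ratio Rsb with its one-tailed -log10 p transform, and overlapping
    sliding-window candidate-region calling under Benjamini-Hochberg FDR
    control. Companion tooling covers genotype quality control (call rate,
    minor allele frequency, Hardy-Weinberg, heterozygosity outliers),
    population structure (VanRaden genomic relationship matrix, PCA,
    Weir-Cockerham F_ST, Ward clustering), variant-level allele-frequency
    contrasts with Fisher's exact test, feature annotation of candidate
    regions, and forward Wright-Fisher simulators that generate structured
    genotypes and two-population phased haplotype panels with a known sweep
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    jsonlite,
    ape,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
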