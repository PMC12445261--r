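Package: adgreml
Title: Additive and Dominance Genomic Analysis for Divergent Selection
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for additive plus dominance genomic analysis
    of small, deeply phenotyped livestock cohorts from divergent selection
    experiments. Simulates pedigrees, genotypes and traits with controlled
    additive and dominance architecture; applies sequence-variant quality
    control (call rate, minor allele frequency, Hardy-Weinberg exact test)
    and LD pruning to obtain the effective number of independent tests;
    builds genomic (additive and dominance) and pedigree-based relationship
    matrices; estimates variance components by average-information REML with
    liability-scale conversion for binary traits; computes BLUP breeding
    values and their correlations; runs a single-variant mixed-model scan
    that tests additive and dominance effects simultaneously; and annotates
    significant variants to candidate genes by a proximity rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
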