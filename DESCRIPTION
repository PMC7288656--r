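Package: aisnp
Title: Evaluation of Ancestry-Informative SNP Panels and Continental
    Ancestry Inference
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate panels of ancestry-informative single
    nucleotide polymorphisms (AISNPs) and to infer continental ancestry
    from unlinked biallelic genotypes.  Implements per-locus divergence
    metrics (one-vs-rest allele-frequency difference, Nei's Gst,
    Rosenberg's informativeness-for-assignment), a naive-Bayes ancestry
    classifier with leave-one-out cross-validation, exact Hardy-Weinberg
    tests, EM-based two-locus linkage disequilibrium, forensic identity
    statistics, Nei's DA distances with neighbor-joining trees, principal
    component analyses, a maximum-likelihood admixture model fitted by EM,
    sequencing coverage quality control, and a Balding-Nichols genotype
    simulator for fully reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
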