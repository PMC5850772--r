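Package: cladecall
Title: Predicting Adaptive Driver Mutations from Glucose-Inducible
    Expression Signatures in Evolved Yeast Clones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for phenotype-to-genotype inference in
    experimentally evolved Saccharomyces cerevisiae. Converts raw qRT-PCR
    cycle-threshold tables for a five-gene glucose-inducible panel (HXT2,
    HXT3, HXT4, HXT6/7, SUC2; reference ACT1) into ancestor-relative log2
    expression ratios with propagated replicate error, clusters clones by
    complete-linkage hierarchical clustering, selects the number of primary
    clades by a within-group sum-of-squares elbow rule, predicts each
    clone's adaptive driver mutation from clade co-membership with
    genotyped clones, quantifies class separation by Fisher linear
    discriminant analysis with 95 percent confidence ellipses, and tests
    for parallel evolution (recurrent mutations in the same gene) with an
    exact binomial null. A seeded synthetic-cohort generator with
    calibrated class signatures makes every stage verifiable without
    strain data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
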