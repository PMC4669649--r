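Package: augcall
Title: Two-Stage Genotype Calling for SNP Arrays with Simulated-Data
    Augmentation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls genotypes (AA/AB/BB) from two-channel SNP-array raw
    intensities using a two-stage procedure aimed at rare variants. Stage
    one estimates three bivariate-Gaussian genotype clusters per SNP from
    quality-control samples with known genotypes, borrowing a nearby
    reference SNP (selected by a Mahalanobis distance on projected
    intensities) when a SNP lacks three well-populated clusters. Stage two
    augments the observed cohort with subjects simulated from the stage-one
    clusters, fits a three-component bivariate Gaussian mixture by
    expectation-maximization, and emits calls gated by per-subject and
    per-SNP posterior-rate thresholds. Includes evaluation utilities (call
    rate, concordance, minor-allele frequency, Hardy-Weinberg equilibrium
    tests, MAF-stratified reports) and a synthetic-data generator for
    two-channel intensity panels with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SNP, GenotypingArray, Genetics, Clustering, StatisticalMethod
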