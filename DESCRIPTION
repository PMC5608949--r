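Package: mfmap
Title: Hierarchical Multifluid Metabolic Correlation Maps and
    Phenotype-Driven Module Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds hierarchical correlation maps from multifluid
    (e.g. plasma, urine, saliva) untargeted metabolomics data and
    searches them for phenotype-associated modules.  Provides the full
    preprocessing chain for raw ion-count matrices (run-day median
    rescaling and filtering, probabilistic quotient normalization,
    log2 transform, robust multivariate outlier exclusion, and
    two-stage imputation combining censored-normal maximum likelihood
    with predictive mean matching), Gaussian graphical model inference
    with shrinkage partial correlations and dual Pearson/partial
    Bonferroni edge selection, eigenmetabolite aggregation of
    sub-pathways with collapsing to super-pathway networks, and a
    greedy, regression-scored module identification algorithm with
    consolidation of overlapping optima and node-level Bonferroni
    significance.  A configurable synthetic multifluid data generator
    with known ground truth (latent pathway factors, dilution, run-day
    batches, left-censoring, planted phenotype effects) supports
    validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    fitdistrplus,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
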