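Package: matealloc
Title: Genomic Mate Allocation with Dominance and Inbreeding Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for genomic evaluation and mate allocation in livestock
    breeding schemes that exploit non-additive genetic effects. Builds
    VanRaden additive and dominance-deviation genomic relationship
    matrices, estimates additive, dominance and permanent-environmental
    variance components by EM-REML (with average-information acceleration)
    under models that include a genomic-inbreeding covariate for directional
    dominance, converts variance components to marker-level variances, solves
    the equivalent SNP-BLUP system for additive and dominance marker effects,
    predicts expected breeding values and total genetic values of the progeny
    of every candidate sire x dam pair from Mendelian genotype probabilities,
    and selects an optimal set of matings by exact linear programming on the
    transportation polytope. Includes a family-structured genotype and
    phenotype simulator and quality-control utilities for SNP data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
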