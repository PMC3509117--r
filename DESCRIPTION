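Package: ystrhap
Title: Y-STR Haplotype Diversity, Median-Joining Networks and Founder Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of Y-chromosome short tandem repeat (Y-STR) haplotype
    tables for phylogeographic inference: within-population diversity
    statistics (haplotype diversity, mean pairwise differences, repeat
    variance, modal haplotypes), between-population distances (mean
    cross-population pairwise differences, Goldstein's (delta-mu)^2, Rst),
    hierarchical analysis of molecular variance (AMOVA) with Phi statistics,
    classical multidimensional scaling of distance matrices, median-joining
    haplotype networks with maximum-parsimony pruning, founder-cluster
    extraction, and rho-statistic / average-squared-distance (TD) time to
    most recent common ancestor estimation. Includes a stepwise-mutation-model
    simulator (star and Kingman-coalescent genealogies) for estimator
    validation and founder-effect scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
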