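Package: wildhyb
Title: Hybridization Analysis for Wildcat and Domestic Cat Microsatellite Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting hybridization between European wildcats
    (Felis silvestris silvestris) and domestic cats (F. s. catus) from
    replicated multilocus microsatellite genotypes. Covers consensus
    genotyping and quality-index filtering of noninvasive samples, diversity
    and differentiation statistics (Weir-Cockerham F-statistics with
    permutation tests, rarefied allelic richness, Hardy-Weinberg, linkage
    and null-allele tests, genotype PCA), Bayesian admixture inference by
    Gibbs sampling with credibility intervals, an EM classifier over hybrid
    genotype-frequency classes (F1, F2, first-generation backcrosses),
    simulation-calibrated hybrid detection with conservative and relaxed
    rules and resampling confidence intervals, maximum-likelihood pairwise
    relatedness, and a synthetic-data generator emulating a two-subspecies,
    two-region sampling design with an allelic-dropout error model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
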