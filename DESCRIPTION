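Package: msatabc
Title: Microsatellite Population Genetics and Approximate Bayesian
    Demographic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diploid microsatellite datasets: GENEPOP input and
    output, observed and unbiased expected heterozygosity, rarefied allelic
    richness, Markov-chain exact tests of Hardy-Weinberg equilibrium,
    genotypic linkage-disequilibrium permutation tests, Lynch-Ritland
    pairwise relatedness with iterative kin pruning, Weir-Cockerham
    F-statistics, allele-size based R_ST with allele-size permutation tests
    for phylogeographic signal, Mantel and partial Mantel tests of isolation
    by distance, and a coalescent simulator for multi-deme divergence
    scenarios with bottlenecks under a generalized stepwise mutation model.
    The simulator feeds an approximate Bayesian computation (ABC) layer:
    reference tables of summary statistics, scenario choice by local
    multinomial logistic regression, parameter estimation by local linear
    regression with logit-transformed bounded parameters, and validation by
    pseudo-observed datasets (type I/II error, relative median absolute
    error, posterior-predictive model checking).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    geosphere,
    yaml,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
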