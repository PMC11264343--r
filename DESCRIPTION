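Package: mastphylo
Title: Phylogenetic Comparative Analysis of Mast-Seeding Intensity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking mast-seeding intensity to plant functional
    traits on a phylogeny. Computes the consecutive disparity index from
    interannual seed-crop series, estimates phylogenetic signal for
    continuous traits (Pagel's lambda by maximum likelihood, with
    likelihood-ratio and randomization tests) and binary traits
    (Fritz-Purvis D with permutation and Brownian-threshold nulls), fits
    Gaussian phylogenetic generalized linear mixed models, computes
    phylogenetically corrected correlations via independent contrasts, and
    partitions variance among predictors and phylogeny with likelihood-based
    partial R-squared. A synthetic-data generator (pure-birth trees,
    lambda-structured continuous traits, threshold or shuffled binary
    traits, AR(1) log-normal seed-crop series) provides known ground truth
    for every stage, and a config-driven pipeline runs the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, stats, utils, yaml
Suggests: testthat (>= 3.0.0), phytools, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
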