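Package: kinskew
Title: Genetic Structure, Relatedness and Reproductive Skew in
    Cooperatively Breeding Groups
Version: 0.1.0
Authors@R:
    person("DMRP", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the genetic structure of cooperatively
    breeding mammal populations genotyped non-invasively at microsatellite
    loci. Provides multi-tube consensus genotyping with allelic-dropout
    resolution, per-locus diagnostics (heterozygosity, polymorphic
    information content, Hardy-Weinberg tests, null-allele frequency,
    probability of identity), hierarchical F-statistics with permutation
    tests, Queller-Goodnight pairwise relatedness with breeder-pair
    permutation and Mantel tests, likelihood-based parentage assignment
    with simulation-calibrated confidence thresholds, an admixture-model
    Gibbs sampler with Evanno delta-K model selection, life-history
    summaries (group-size interpolation, mean-of-means season summaries,
    dispersal and survival tallies, expected-skew nulls), and a seeded
    pedigree-and-genotype simulator that provides ground truth for every
    estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
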