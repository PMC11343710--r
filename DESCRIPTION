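Package: dynastikin
Title: Kinship, Consanguinity and Latent-Pedigree Inference for Ancient DNA
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genotype-level kinship analysis of low-coverage
    ancient-DNA data and Bayesian selection among candidate pedigrees
    linking two individuals. Implements the pairwise mismatch rate on
    pseudo-haploid EIGENSTRAT genotypes with Bayesian relatedness-degree
    classification, chromosomal sex determination from relative X/Y
    coverage, a sex-biased-admixture Z statistic, runs-of-homozygosity
    consanguinity summaries, identity-by-descent sharing summaries with
    simulation-based degree envelopes, exact two-sided Wilcoxon rank-sum
    tests by dynamic programming, and a latent-variable pedigree model
    that combines archaeological burial dates, osteological ages at
    death, autosomal kinship and mitochondrial haplotype matching into
    posterior weights and Bayes factors over a catalogue of candidate
    pedigrees via Monte-Carlo marginal likelihoods and MCMC. A
    synthetic-data module (gene dropping, pseudo-haploidization,
    Poisson-recombination segment simulation, matrilineal haplotype
    transmission and chronological observation generators) makes every
    stage testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
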