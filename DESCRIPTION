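Package: hzclines
Title: Hierarchical Bayesian Genomic Clines and Admixture Inference for
    Hybrid Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian estimation of hybrid indexes, ancestry-class
    proportions, and hierarchical logit-logistic genomic clines for hybrid
    zone population genomics. Models accept known genotypes, genotype
    likelihoods (e.g., from low-coverage sequencing), or local-ancestry
    calls, with mixed haploid/diploid loci. Posterior sampling uses a
    built-in No-U-Turn Hamiltonian Monte Carlo sampler with compiled model
    gradients. Includes individual-based secondary-contact hybrid zone
    simulations with underdominant selection, a generative cline
    simulator, and a read-depth genotype-likelihood simulator, plus
    recovery metrics (mean absolute error, credible-interval coverage)
    for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    coda,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
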