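Package: chronosite
Title: Fast Bayesian Divergence-Time Estimation on Fixed Topologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bayesian inference of species divergence times on a fixed,
    rooted binary topology from multi-gene DNA alignments.  The exact
    phylogenetic likelihood is computed with subtree site-pattern
    compression: every inner node deduplicates the site patterns projected
    onto its own leaf set, so each unique subtree pattern's partial
    likelihood is evaluated once.  The birth-death-sampling
    order-statistics prior on node ages is maintained incrementally across
    MCMC proposals through an age-sorted pointer vector and per-segment
    conditional-density caches, instead of being rebuilt from scratch at
    every step.  Includes an HKY+Gamma substitution model, soft-bound
    fossil calibrations, a Metropolis-Hastings sampler with independent
    log-normal branch rates, a synthetic-data generator, and brute-force
    oracles for both bespoke algorithms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
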