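Package: cophylotest
Title: Host-Parasite Phylogenetic Congruence Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests whether a parasite (or symbiont) phylogeny is congruent
    with its host phylogeny, as used to detect host switching in vertically
    transmitted viruses. Provides maximum-likelihood and Bayesian tree
    inference under GTR-family substitution models with gamma-distributed
    rate variation and invariable sites (Felsenstein pruning likelihood,
    nearest-neighbour-interchange search, Metropolis-Hastings MCMC over
    topologies), and three congruence tests: a Shimodaira-Hasegawa test
    against a host-constrained topology, the proportion of the posterior
    topology sample matching the host tree, and a Robinson-Foulds
    random-topology null. A cophylogeny simulator (Yule host trees,
    host-switch SPR events, sequence evolution under the fitted models)
    makes every stage testable on synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse
Config/testthat/edition: 3
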