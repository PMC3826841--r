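Package: logicyc
Title: Multi-Valued Logical Simulation of the Yeast Cell Cycle Under
    Gene-Dosage Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-time, synchronous, multi-valued logical-network
    simulator of the Saccharomyces cerevisiae cell cycle. Gene copy-number
    variation is modelled as per-occurrence stochastic resets of node
    values, so fractional dosages (tetraploid deletion series, hypomorphic
    alleles, kinase inhibitors) can be titrated continuously. The package
    ships an extended 52-node cell-cycle model, computes relative growth
    rates by cytokinesis-event counting, assembles wild-type-normalised
    cell-cycle phase profiles, derives flux-control coefficients from
    dosage series, and validates the stochastic engine against an exact
    Markov-chain enumeration oracle on small models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
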