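Package: bnss
Title: State-Space Census and Frozen-Node Analysis of Stochastic Boolean
    Regulatory Networks
Version: 1.0.0
Authors@R:
    person("Ana", "Weiss", email = "ana.weiss@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of logical (Boolean) models of
    regulatory networks under a hybrid update scheme in which most nodes
    follow deterministic logical rules while "free" nodes receive an
    independent random state at every update.  Provides a rule-file
    parser with clamping (in-silico knockout) support, synchronous and
    sequential trajectory simulation, a state-space census (visit
    frequencies of distinct network states, identified by Hamming
    distance zero), frozen/variable node classification, synchrony-group
    detection, pairwise joint-state census, response-efficiency curves,
    and mutant-network comparison.  An exact Markov-chain oracle
    enumerates the full transition structure of small networks
    (stationary distributions, recurrent classes) to validate every
    sampling-based statistic.  A command-line interface exposes the
    complete simulate/analyze/mutants workflow with reproducible
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
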