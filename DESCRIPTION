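Package: indelsim
Title: Fast Simulation of Indels and Substitutions Along Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gillespie simulation of insertion and deletion (indel) events along
    the branches of a rooted phylogenetic tree, with three interchangeable
    bookkeeping engines: a naive explicit-sequence engine, a run-length block
    list, and an order-statistic AVL block tree. Indels and substitutions are
    simulated independently and superimposed, and the true multiple sequence
    alignment implied by the simulated event history is assembled through a
    super-sequence of all positions that ever existed. Includes truncated
    Zipfian and geometric indel length distributions, edge-effect-corrected
    deletion placement, a JTT-based amino-acid substitution simulator,
    reproducible synthetic tree fixtures, and an operation-count benchmark
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
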