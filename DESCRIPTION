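Package: nitrofate
Title: Pathway Partitioning of Dissimilated Nitrogen in Dual-Pathway Nitrite Reducers
Version: 0.1.0
Authors@R:
    person("Nitrofate", "Developers", email = "nitrofate@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying how a dual-pathway bacterium
    partitions nitrite between respiratory ammonification (DNRA) and
    denitrification. Provides protein side-chain elemental cost statistics
    (ARSC) with permutation inference, exact balancing of donor/acceptor
    redox couples with biochemical-standard Gibbs free energies, a
    configurable proton-translocation ledger for branched electron transport
    chains built on menaquinone, nitrogen mass-balance and pathway-fraction
    calculations from metabolite time series, growth-rate estimation from
    optical density curves, and a seeded two-phase Monod batch-culture
    simulator that generates fully ground-truthed synthetic data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
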