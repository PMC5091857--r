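Package: delimkit
Title: Integrative Molecular Species Delimitation for Barcode Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative species delimitation from single-locus
    barcode alignments: Kimura two-parameter distances with pairwise deletion
    and explicit saturation flags, barcode-gap discovery with recursive
    partitioning (ABGD-style), the single-threshold generalized mixed
    Yule-coalescent (GMYC) model on ultrametric gene trees, rule-based
    reconciliation of discordant delimitations, classification of delimited
    units into nominal species, confirmed and unconfirmed candidate species
    and deep conspecific lineages, and cryptic-diversity richness statistics.
    Includes a multispecies-coalescent simulator (Yule species tree,
    within-species coalescent, K2P sequence evolution, stochastic evidence
    tables) for validating the full pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
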