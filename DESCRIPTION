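Package: neutraldiv
Title: Neutral Community Assembly and Phylogenetic Diversification of
    Host-Associated Microbiota
Version: 0.1.0
Authors@R: person("neutraldiv", "developers", role = c("aut", "cre"),
    email = "neutraldiv@example.org")
Description: Tools for testing whether a host-associated microbial
    metacommunity assembles neutrally and whether host-restricted lineages
    show reduced phylogenetic diversification.  Implements the Sloan
    occupancy-abundance neutral community model with exact binomial
    per-taxon selection classification, a resampling-based null model for
    phylogenetic neighbor counts and the derived diversification index
    (ADI), community table conditioning (rarefaction, prevalence
    filtering, centered log-ratio transform, accumulation curves), and
    self-contained diversity statistics (Bray-Curtis, Aitchison,
    unweighted/weighted UniFrac, Faith's PD, PCoA, ANOSIM, dispersion
    homogeneity, rank tests).  A synthetic-data module generates
    communities, phylogenies and aligned sequences with known ground
    truth so every stage can be validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    withr,
    ape,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    igraph
Config/testthat/edition: 3
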