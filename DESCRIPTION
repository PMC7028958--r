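Package: ovoseed
Title: Tracking Engraftment of a Donor Cecal Microbiota Applied to the Egg Surface
Version: 0.1.0
Authors@R:
    person("Ovoseed", "Maintainers", email = "maintainers@ovoseed.dev", role = c("aut", "cre"))
Description: Analysis chain for microbiota-transplant experiments in which adult
    cecal content is sprayed onto eggs and chick cecal communities are profiled by
    16S amplicon sequence variants (ASVs) over time. Provides ASV count-table
    handling (presence sets, first-quartile abundance filtering, rarefaction),
    alpha and phylogenetic beta diversity (Shannon, unweighted and weighted
    UniFrac) with the associated group statistics (pairwise Kruskal-Wallis with
    FDR, ANOSIM, donor-distance t tests), a compositional differential-abundance
    workflow built on isometric log-ratio balances from Ward correlation
    clustering with multivariate ordinary least squares, a presence-based
    transplant-success classifier with UpSet-style intersection summaries and a
    chi-square test of independence, delta-CT quantitative PCR relative
    abundance, and a synthetic-data generator that emulates the engraftment
    structure so the whole chain is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
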