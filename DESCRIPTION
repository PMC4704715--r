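Package: atpscreen
Title: Analysis of a Genome-Wide Yeast Extracellular-ATP Screen
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse a genome-wide deletion-library screen of
    extracellular ATP levels measured by luciferase luminescence in 96-well
    plates. Implements the normalization chain (well-specific blank
    background, plate-reader linear-range exclusion, log2 relative
    luminescence per cell, per-well positional centering across plates),
    replicate averaging with validity rules, rank-tail hit calling,
    exact hypergeometric gene-set enrichment with fold-enrichment and
    redundancy trimming, functional-interaction subnetwork connectivity
    and module statistics, and retest/time-course fold-change and t-test
    statistics. Includes a synthetic-screen generator (plates, plate maps,
    planted strain effects, annotation collections, interaction networks,
    retest tables) so the full pipeline can be exercised and calibrated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
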