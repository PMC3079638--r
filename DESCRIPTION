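Package: capnet
Title: Compartment-Annotated Signaling Network Topology and Virtual Knockouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing undirected signaling networks whose nodes
    are annotated with subcellular compartments. Reads and writes Cytoscape
    SIF edge lists with node-attribute tables, computes the classical
    topology statistic bundle (clustering coefficients, diameter,
    characteristic path length, average neighbors, closeness centrality)
    together with log-log least-squares power-law fits of the degree and
    clustering-coefficient spectra, detects nodes whose neighborhoods
    bridge a target set of subcellular compartments, and performs virtual
    node knockouts that report nodes orphaned from the giant component.
    Includes seeded generators for compartment-labeled preferential
    attachment networks and planted-bridge networks with known ground
    truth, a documented capacitation-core fixture network, a spring
    embedded (force-directed) layout utility, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
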