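Package: fluxmark
Title: Metabolite Biomarker Discovery from Flux Intervals and Reaction
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate reaction, gene and metabolite biomarkers
    in genome-scale metabolic models by integrating condition-specific gene
    expression with constraint-based flux analysis.  Two complementary
    pipelines are provided: flux profile comparison (FPC), which tightens
    reaction flux capacities by expression-derived activity probabilities,
    computes per-reaction flux intervals by flux variability analysis under
    normal and disease conditions and flags reactions whose intervals
    diverge; and a reaction-reaction network (RRN) pipeline, which links
    reactions sharing a metabolite, extracts the largest k-means cluster,
    ranks reactions by an unnormalized PageRank recursion and scores them
    by the product of rank and flux magnitude.  Includes readers for SBML,
    BiGG-style JSON and a plain tab-separated model dialect, a parser for
    bracketed reaction-equation strings, Cytoscape-compatible SIF/GraphML
    export, and a generator of small stoichiometrically consistent
    synthetic models with paired expression profiles and planted
    differential reactions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
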