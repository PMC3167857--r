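Package: modpath
Title: Disease Gene Interaction Pathways from Hierarchical Network Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies disease gene interaction pathways in protein-protein
    interaction networks. Proteins are agglomeratively clustered into a
    lossless hierarchical tree of modules by maximal Jaccard neighborhood
    similarity; the tree is then searched bottom-up for the first hierarchy
    at which the modules containing disease proteins ("disease-risk
    modules") form a connected pathway through module-module interactions.
    Includes degree-preserving network randomization for significance
    assessment, exact hypergeometric term enrichment of modules with
    shared-function analysis of interacting module pairs, and a synthetic
    planted-module network generator for end-to-end validation without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
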