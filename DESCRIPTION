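Package: pathtopo
Title: Topological Detection of Intermediate Protein Conformations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects candidate intermediate states along large-scale protein
    conformational transitions. A biased coarse-grained Monte-Carlo search
    over C-alpha pseudo-dihedrals generates a pathway between two endpoint
    structures; the conformational cloud is reduced by spherical PCA or
    Isomap; and a persistent-homology based hierarchical clustering (maxmin
    landmarks, lazy witness filtrations, degree-0/1 barcodes, bar-gap cluster
    selection) extracts well-separated nested clusters and reports their
    RMSD statistics against the endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
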