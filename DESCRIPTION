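Package: allosite
Title: Geometric Screening of Cross-Subunit ATP Allosteric Sites and the
    Phosphoketolase ATP-Regulatory Sequence Motif
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects the cross-subunit "aromatic sandwich" mode of adenine
    nucleotide binding in protein structures by a two-criterion geometric
    screen (adenine C5 to aromatic CG distance; gamma-phosphate PG to
    arginine CZ distance) with pi-pi stacking assessment and tiered site
    classification. Also scans protein sequences for the eight-anchor
    ATP-regulatory motif of phosphoketolases, filters sequence families by
    global percent identity, builds position frequency matrices and
    information-content profiles around the motif anchors, computes
    p-distance neighbor-joining trees with Newick output, and performs
    Kabsch C-alpha superposition with RMSD reporting. A synthetic-data
    module generates ground-truth-labelled binding-site structures and
    motif-bearing sequence families so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
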