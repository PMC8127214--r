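Package: treepin
Title: Data-Dependent Resolution for Tree-Structured Hypotheses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential abundance and differential state analysis on a
    hierarchy of entities (taxa, miRNAs, cell subpopulations). Leaf-level
    measurements are aggregated to every node of a rooted tree, each node is
    tested for a group difference, and a score combining significance and
    direction of change is used to propose candidate resolutions of the tree.
    Candidates are corrected for multiplicity individually and the best one is
    selected in a data-driven way that controls the false discovery rate on
    the leaf level. Includes a Dirichlet-multinomial count simulator with
    tree-located signal scenarios and leaf-level TPR/FDR benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    edgeR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
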