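Package: tripath
Title: Tripeptide-Database Path Search for Protein Conformational Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sequence-specific tripeptide libraries of protein backbone
    dihedral angles from experimentally determined structures, organises each
    library as an adjacency graph with a conformational density measure, and
    computes feasible folding and transition pathways between protein
    conformations with a heuristically guided depth-first search over the
    product of tripeptide domains. Includes rigid-geometry backbone
    reconstruction, angular RMSD metrics on the torus, cell linked-list
    steric collision detection with side-chain pseudo-atoms, incremental
    ensemble sampling of collision-free states, synthetic fixture generators
    with exhaustive-search certificates, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
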