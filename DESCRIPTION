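Package: zfAIR
Title: Ambiguous Interaction Restraints for Docking Zinc-Finger Proteins
    onto DNA
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and vets ambiguous interaction restraints (AIRs) for
    information-driven docking of three-Cys2His2 zinc-finger proteins onto
    DNA, and evaluates the resulting complex models. Provides canonical
    B-DNA construction from sequence, zinc-finger domain annotation,
    pairwise and non-pairwise restraint sets with the two-restraints-per-
    domain selection heuristic, DNA helix-axis projection analysis of the
    geometric balance of a restraint set, and CAPRI-style evaluation of
    docked models (wrap-around classification, restraint-violation energy,
    fraction of native contacts, interface RMSD, buried surface area,
    score-based ranking). Synthetic wrapped/mismatched complex generators
    make every stage testable without external structures or a docking
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
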