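Package: pathweaver
Title: Rigidity-Guided RRT* Sampling of Protein Conformational Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Samples conformational transition pathways between two
    experimentally determined conformations of the same protein with a
    hybrid RRT*/Monte-Carlo tree search in backbone dihedral space.
    Proteins are reduced to a semi coarse-grained representation
    (backbone plus C-beta); candidate moves perturb phi/psi torsions,
    are relaxed by a bounded steepest-descent minimization of a soft
    coarse-grained potential, and are admitted by an energy gate and a
    Monte-Carlo criterion.  A built-in body-bar pebble-game rigidity
    analysis decomposes each conformation into rigid clusters so the
    search can restrict perturbation to flexible residues, either once
    at the start or adaptively as the conformation drifts.  Includes a
    synthetic fixture generator (ideal-geometry peptides with
    engineered hinges), PDB input/output for single conformations and
    multi-model pathways, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
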