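Package: raftbind
Title: Analysis of Amyloid Oligomer Binding to Phase-Separated Raft Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trajectory-analysis toolkit for studying how tau, amylin and
    hetero tau-amylin oligomers bind to asymmetric, phase-separated raft
    bilayers containing anionic phosphatidylserine or ganglioside GM1
    clusters. Implements liquid-ordered/disordered/boundary (Lo/Ld/Lod)
    lipid domain classification by atom-proximity rules, annular-shell
    extraction, minimum-distance binding kinetics and per-residue spectra,
    acyl-chain orientational order profiles, cutoff-bounded Lennard-Jones
    and Coulomb group energetics, Kyte-Doolittle hydropathy profiles, DSSP
    secondary-structure regrouping, and time-averaged residue contact maps,
    together with a seed-deterministic synthetic membrane and binding
    trajectory generator that stands in for coarse-grained and all-atom
    molecular dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
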