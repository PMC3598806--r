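Package: efswitch
Title: Trajectory Metrics for the EF-Hand Calcium Switch of Troponin C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies calcium-dependent opening and closing of the
    troponin-C N-lobe from protein structures and trajectories in PDB
    format: hydrophobic-pocket openness with open/semi-closed/closed state
    classification, calcium-binding-site expansion, the position-12
    glutamate "prong" hydrogen bonds, dwell-filtered hydrogen-bond
    breakage/reformation events and the beta-sheet scaffold report,
    per-residue C-alpha root-mean-square fluctuation after least-squares
    superposition, inter-lobe rotation via virtual dihedral angles,
    hydrophobic contact persistence and Shrake-Rupley solvent-accessible
    surface area. Includes a deterministic synthetic-trajectory generator
    for ground-truth validation and a config-driven analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
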