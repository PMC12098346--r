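Package: structscope
Title: Structural Triage of G-Protein Beta-Gamma Effector Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Geometric and thermodynamic analysis of protein-protein
    complexes, built around the workflow used to interpret disease
    mutations at G-protein beta-gamma effector interfaces: interface and
    contact detection at a 5.5 Angstrom heavy-atom cutoff, focal-residue
    interaction networks with rule-based non-covalent edge typing, a
    simplified template-based point mutant builder, membrane-geometry
    triage of docked poses against leaflet planes, and classification of
    predicted stability and affinity changes against significance and
    thermal-noise thresholds with conversion to dissociation-constant
    fold change. Includes a deterministic synthetic-fixture generator so
    every stage is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
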