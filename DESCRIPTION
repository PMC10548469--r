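Package: synthsearch
Title: Grid-Based Systematic Search of Cohesive and Adhesive Crystal
    Interaction Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synthonic engineering of particulate solids: parse
    crystal structures from CIF files, expand symmetry and detect molecular
    units, build Miller-indexed surface slabs with attachment-energy
    termination scanning and BFDH face ranking, and run exhaustive rigid-body
    grid searches (molecule-molecule, molecule-surface, surface-surface) with
    a Dreiding-style atom-atom force field. Pose energies are decomposed into
    dispersive, electrostatic and hydrogen-bond contributions, normalized per
    probe atom, and aggregated into cohesive-adhesive balance reports that
    predict whether a binary powder blend (for example a dry-powder-inhaler
    drug and its carrier excipient) will segregate or remain intimately mixed.
    Deterministic toy-crystal generators make every stage testable without
    external structure databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
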