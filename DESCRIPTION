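Package: porelock
Title: Open-State Pore Restraints and Trajectory Annotation for Pentameric
    Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates flat-bottom cross-pore distance restraints and staged
    equilibration schedules used to refine open-state structures of pentameric
    ligand-gated ion channels, and annotates molecular dynamics trajectories of
    such channels: HOLE-style pore radius profiles, Wimley-White hydrophobicity
    profiles, pore hydration and dewetting, ion permeation event counting and
    selectivity, 3D number-density grids, per-residue RMSF, hydrophobic-pocket
    burial of the 9' gate and proline-ring pairing at the -2' gate. Includes a
    synthetic fixture generator producing idealized pentameric pores and
    scripted particle trajectories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
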