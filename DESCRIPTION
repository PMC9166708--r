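Package: hjkit
Title: Sequence Combinatorics, Geometry and Ion-Binding Analysis of DNA
    Holliday Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of four-way (Holliday) DNA junctions as
    used in self-assembling 3D DNA crystals. Enumerates the 36 rotationally
    distinct immobile branch-point sequences via an explicit strand-exchange
    (branch-migration) model, measures the signed interhelical angle (J-twist)
    of stacked-X junctions with a handedness convention, detects monovalent
    ion bridging at the two conserved branch-point sites and summarizes
    per-trajectory binding incidence, and models lattice cavity volumes and
    unit-cell group statistics. A synthetic-structure generator builds
    idealized stacked-X junction coordinates and trajectories with known
    ground truth so every analysis can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
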