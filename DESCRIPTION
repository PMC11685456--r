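Package: strucdyn
Title: Structural Dynamics Analysis for Chaperone Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying conformational dynamics of multi-domain
    protein complexes such as the mitochondrial Hsp70 (mortalin) - GrpEL1
    nucleotide-exchange system. Provides fixed-column PDB and multi-model
    trajectory input/output with named domain selections; Kabsch least-squares
    superposition with per-domain and per-atom RMSD series; quantification of
    inter-subdomain rotations, helical stalk bending and centroid
    displacements; Shrake-Rupley solvent-accessible and buried interface
    surface areas with residue contact classification; a from-scratch
    anisotropic network model (Hessian construction, low-frequency modes,
    all-atom mode extension, mean-square fluctuations and cross-correlations);
    kernel-density and substate-occupancy analysis of anchor-defined
    trajectory angles; seeded synthetic-structure and trajectory generators
    with known ground truth; and a configuration-driven analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
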