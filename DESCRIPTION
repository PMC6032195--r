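Package: groovedyn
Title: Geometry and Dynamics of the MHC Class II Peptide-Binding Groove
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of structure ensembles of MHC class II molecules and
    of ligands bound in their peptide-binding groove. Reads and writes
    (multi-model) PDB files; performs Kabsch superposition, RMSD and
    per-residue RMSF analysis and medoid representative-structure
    selection; computes the inter-helical distance metric of groove
    opening/closing with mean, standard deviation and drift-slope
    summaries; derives voxel occupancy volumes of bound ligands and
    peptides; maps drug-induced peptide displacements; scans peptide
    registration frames along the groove axis with P1-P9 pocket
    assignment; provides molecular-mass and concentration arithmetic; and
    analyses competitive binding assays with a two-tailed Dunnett
    many-to-one test. Includes a synthetic groove-trajectory generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    jsonlite
Config/testthat/edition: 3
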