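Package: critres
Title: Critical Protein Residue Detection by Rigidity and Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects critical residues in protein structures by combining two
    complementary signals. A body-bar-hinge mechanical model is built from the
    covalent bonds, hydrogen bonds and hydrophobic tethers of a PDB structure,
    its generic rigidity is decided with the (6,6) pebble game, and residues
    are mutated in silico to glycine or alanine by removing the constraints
    their side chains contribute; the percentage decrease of the largest rigid
    body scores the residue's mechanical importance. Independently,
    Evolutionary Trace residue ranks are converted to a per-chain conservation
    z-score. Both flags are combined into per-residue verdicts, compared
    against experimental unfolding free-energy changes, and summarised per
    protein and per cohort. Includes deterministic generators for toy
    structures, random body-bar multigraphs and synthetic rank files, a dense
    rigidity-matrix oracle for validating the pebble game, and curated
    published benchmark tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
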