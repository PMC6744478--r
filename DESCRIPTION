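Package: xlcal
Title: Crosslink-Calibrated Structural Model Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for evaluating protein structure models against
    crosslinking mass spectrometry (XL-MS) data. Maps DSSO lysine-lysine
    crosslinks onto sequences and 3D models, builds and scores N-zeta
    distance restraints, ranks docking decoys by restraint satisfaction,
    superposes models with and without iterative outlier rejection,
    computes solvent-accessible and buried surface area, locates insert
    regions in multiple sequence alignments with hydropathy and charge
    comparison, and simulates and fits 1:1 Langmuir SPR sensorgrams.
    Deterministic synthetic-fixture generators make the full workflow
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
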