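Package: decoyrank
Title: Template-Injection Estimation of Protein Model Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate ("decoy") protein structures by predicted
    accuracy using a template-injection protocol: a decoy is encoded as a
    sequence-free structural template (gap-token sequence, C-beta distance
    matrix, backbone torsions, atom masks), submitted to a pluggable
    structure predictor, and scored by a composite confidence score (the
    product of mean pLDDT, pTM and the TM-score between the decoy and the
    predictor output). Includes native implementations of TM-score, GDT_TS
    and lDDT, per-target ranking statistics (Spearman correlation, top-1
    GDT_TS loss, Z-scores), two application protocols (structure search via
    a generator-discriminator loop, fixed-backbone sequence design through a
    distogram cross-entropy loss), a synthetic decoy-ladder generator, and
    deterministic mock predictors so every stage runs without model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
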