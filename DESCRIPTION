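Package: scdistill
Title: Structure-Consistency Distillation for Protein Sequence Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for distilling protein folding-model confidence metrics
    into a fast sequence-to-score model and using the distilled score as a
    structure-consistency regularizer when training sequence design models.
    Includes reference implementations of TM-score and lDDT from alpha-carbon
    coordinates, curation utilities for scored-sequence datasets (binned
    discretization, similarity filtering, cropping, augmentation, balance
    filtering, inverse-frequency sampling weights), a small trainable
    sequence-to-bin classifier with focal loss, the combined cross-entropy
    plus structure-consistency objective, sequence design evaluation metrics
    (recovery, diversity, perplexity, core/surface breakdowns), and synthetic
    generators for backbones, scored sequences and a toy structure-conditioned
    design task.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
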