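Package: dropvision
Title: Crystal Detection in Crystallization Drop Micrographs with
    Low-Rank Adapted Vision Transformers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated identification of protein crystals in
    crystallization drop micrographs. Provides a procedural generator for
    paired visible/UV synthetic drop images with ground-truth manifests, a
    manifest data model with the class-consolidation and plate-sampling rules
    used to assemble crystallization training sets, a configurable vision
    transformer classifier with from-scratch low-rank adaptation (LoRA),
    an imbalance-aware fine-tuning recipe (inverse-frequency weighted
    cross-entropy, linearly decaying learning rate), visible/UV score fusion,
    evaluation metrics suited to heavily imbalanced screens, and a
    human-in-the-loop curation workflow that turns user/model scoring
    discrepancies into versioned curated training sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
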