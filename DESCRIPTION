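Package: remex
Title: Hybrid Residual-Recurrent Relation Extraction for Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Character-level relation extraction for clinical narratives
    built around a hybrid neural encoder: a residual convolutional branch
    for local multi-scale features, a bidirectional gated-recurrent branch
    for long-range dependencies, and attention pooling over each branch
    fused for softmax classification over a clinical relation schema
    (treatment, disease, symptom, test, body-position entities; seven
    entity-pair categories and eleven relation labels plus "unknown").
    Includes corpus I/O and candidate-pair generation, skip-gram character
    embedding pretraining, supervised training with Adam, a
    confidence-threshold bootstrapping (self-training) loop for
    semi-supervised corpus expansion, per-class precision/recall/F1
    evaluation excluding the "unknown" class, and a synthetic corpus
    generator with planted relation triggers for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
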