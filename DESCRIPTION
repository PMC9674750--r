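Package: crossmap
Title: Zero-Shot Language-to-Vision Mapping for Word Meanings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how visual representations can be
    extrapolated for words without direct visual experience. Implements a
    linear zero-shot mapping from distributional word vectors onto
    SVD-reduced visual feature vectors in prototype and exemplar training
    regimes, semantic-neighborhood metrics over visually grounded training
    items, item-selection procedures for factorial and decorrelated designs,
    a two-alternative forced-choice response simulator with crossed random
    effects, and mixed-effects logistic analysis with likelihood-ratio model
    comparison and marginal/conditional R-squared. A synthetic-world
    generator produces coupled language/vision spaces so the full pipeline
    runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
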