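Package: mnemosharp
Title: Pseudopopulation Decoding and Sharpening Analysis for Mnemonic
    Similarity Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing recognition-memory experiments in which
    subjects judge images as novel or repeated in the presence of visually
    similar lures. Implements representational dissimilarity from model
    feature vectors, lure-pair selection, session screening, unit d-prime,
    pseudopopulation assembly across sessions, cross-validated spike-count
    and prototype (weighted) linear decoders, percent-chose-repeat curves,
    a weighted signed-area sharpening metric with sliding-window dynamics
    and latency comparisons, and a Poisson spiking-data simulator with
    known ground-truth memory-transfer functions so the full chain is
    verifiable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
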