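Package: bioscope
Title: Rule-Based Composition of Biological Events with Negation and
    Speculation Scope
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-phase, rule-based system for extracting biological
    events from the molecular biology literature. The first phase turns
    per-sentence syntactic dependency parses, gold entity annotations and
    a trigger lexicon into a document-level semantic embedding graph, and
    composes predications bottom-up with scalar modality values, polarity
    composition, argument propagation and deterministic coreference
    resolution (relative, appositive, pronominal and sortal anaphora).
    The second phase maps the composed predications to BioNLP shared-task
    style event and Speculation/Negation annotations in standoff format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
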