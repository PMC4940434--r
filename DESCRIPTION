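Package: belscore
Title: Parsing, Validation and Cascade Evaluation of Biological
    Expression Language Statements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for working with the restricted Biological Expression
    Language (BEL) sublanguage used in community evaluations of causal
    relation extraction from biomedical text. Provides a tokenizer,
    recursive-descent parser and validator for BEL statements over the
    HGNC, MGI, EGID, GOBP, MESHD and CHEBI namespaces; the evaluation
    simplification rules (entity equivalence mapping, activity-function
    collapsing, modification and translocation argument stripping,
    direct/indirect relation merging); a multi-level "cascade" scorer
    that credits predictions at the term, function, relationship and
    full-statement levels with micro-averaged precision, recall and
    F-measure and placeholder-aware false-negative accounting; a mean
    average precision evaluator for ranked evidence retrieval with
    worst/random/best ranking bounds; and a grammar-driven synthetic
    corpus generator with controlled prediction perturbations for
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
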