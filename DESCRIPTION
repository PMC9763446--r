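Package: causaltext
Title: Entity-Conditioned Causal Inference over Free-Text Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for screening candidate causal factors of a
    binary clinical endpoint from free text. Sentences are labeled with the
    endpoint, a probabilistic bag-of-words classifier estimates the
    conditional endpoint probability per sentence, a gazetteer recognizes
    biomedical named entities, and an interventional (do-operator style)
    contrast compares predicted probabilities between sentences that do and
    do not mention each entity using a one-tailed z-test with multiplicity
    adjustment. Includes rank-overlap (POT) robustness evaluation across
    repeated runs, a knowledge-based causal tree for stratifying
    drug-induced liver injury patients by R score and severity, and a
    synthetic corpus generator with planted causal entities for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
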