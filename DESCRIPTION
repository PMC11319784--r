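Package: notesect
Title: Schema-Driven Clinical Note Section Identification with Large
    Language Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Identifies and labels the sections of clinical notes
    (discharge summaries, progress notes) by prompting a generative
    language model with free-text section definitions and grounding its
    output back to character spans.  Provides schema loading and label
    mapping, four-component prompt assembly, a pluggable model backend
    with format-checked retries, the span-resolution postprocessing
    algorithm with exact, case-insensitive, and Levenshtein-fuzzy
    matching variants, a partial-overlap span evaluation metric with
    micro aggregation and per-type reports, and a synthetic sectioned
    note and noisy-response simulator so the whole pipeline can be
    exercised offline without restricted clinical corpora or a hosted
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    curl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
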