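Package: termrank
Title: Learning to Rank Medical Terms in Clinical Notes by Importance to Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Extracts candidate medical terms from free-text clinical notes by
    greedy longest dictionary match against a controlled vocabulary and ranks
    them by their importance to the patient with a pairwise ranking support
    vector machine. Implements the full feature suite used for this task
    (frequency, term structure, position, lexical and part-of-speech baseline
    features; word-embedding, semantic-type, consumer-health-vocabulary and
    topic-coherence features), a probability random-forest baseline, and the
    matching evaluation protocol (relaxed string match, precision/recall/F at
    rank n, per-note AUC-ROC over extracted candidates and over all gold terms,
    cross-validation, paired t tests). A synthetic-corpus generator emulates
    the published corpus statistics so the whole pipeline can be exercised and
    benchmarked without access to protected clinical text.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
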