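Package: bilex
Title: Bilingual Lexicon Induction with Character- and Word-Level Neural Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines term translations from document-aligned comparable corpora by
    framing bilingual lexicon induction as binary classification over word and
    phrase pairs. Couples fixed word-level embeddings (skip-gram with negative
    sampling, and a pseudo-bilingual merged-document variant) with a jointly
    trained character-pair recurrent encoder, trained with negative sampling and
    evaluated with edit-distance plus cosine candidate generation and
    threshold-tuned F1 in top and all modes. Includes collocation-based phrase
    extraction, handcrafted edit-distance baselines, similarity-based baselines,
    and a synthetic benchmark generator with controllable cognate and topical
    signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
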