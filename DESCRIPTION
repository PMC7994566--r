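Package: fluencyEF
Title: Comprehensive Semantic Verbal Fluency Features for Predicting Executive Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a comprehensive 43-feature profile from coded,
    time-stamped semantic verbal fluency transcripts (sum scores, error
    types, speech-latency interval profiles, and taxonomy- and
    embedding-based semantic relatedness) and predicts executive-function
    test scores with a confound-corrected repeated cross-validation random
    forest procedure, including out-of-bag permutation feature importance
    and a comparison against the classical sum-score evaluation. Ships
    pluggable lexical-semantic backends (shortest-path taxonomy similarity
    and word-vector cosine similarity), readers for transcript tables and
    Praat TextGrids, and a synthetic cohort generator with latent abilities
    driving word production, latency profiles, error injection and noisy
    executive-function scores under demographic confounding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
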