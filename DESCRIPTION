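Package: pillidr
Title: Pill Identification by Imprint Recognition and Similarity Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step pill-identification pipeline: a recognition step that
    detects imprinted characters with their 2D coordinates, classifies a
    pill's shape, colour and form with a multitask network, and corrects the
    noisy unordered character set with a coordinate-encoded attention-based
    bidirectional character-level sequence-to-sequence model; and a retrieval
    step that ranks candidate pills in a database by a five-term similarity
    score (three feature-match terms, normalized edit similarity and multiset
    character overlap). Includes a synthetic reference-image generator with
    exact ground-truth character boxes so the whole system can be trained and
    evaluated end to end without external pill databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
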