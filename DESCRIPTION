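Package: npscore
Title: Fragment-Based Natural Product Likeness Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies a fragment-based natural product (NP)
    likeness score for small molecules. Molecules are curated
    (stereochemistry removal, largest connected component, element and
    size filters, InChI-based deduplication), linear and circular sugar
    moieties are detected and removed, and every atom environment is
    encoded as a canonical atom signature of configurable height. Per
    fragment log-ratio frequency scores are learned from labelled
    corpora of natural products and synthetic molecules, and arbitrary
    molecules are scored as the size-normalised sum of their fragment
    scores, with and without sugar moieties. Includes a relational
    file-backed store for molecules, fragments and their relations, a
    deterministic synthetic corpus generator for testing, corpus-level
    statistics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
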