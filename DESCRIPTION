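Package: obsmine
Title: Mine Biodiversity Observation Snippets from Literature Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless text-mining toolkit for discovering sentence-level
    biodiversity observations (biotic interactions, traits, natural-history
    notes) inside a corpus of scientific literature. Loads plain-text and
    machine-readable PDF files, normalizes publisher artifacts (line-break
    hyphenation, typographic ligatures), splits text into sentences and
    tokens, recognizes Latin scientific names with a local rule-based
    recognizer (including genus-abbreviation resolution and optional
    higher-rank annotation from a user-supplied taxonomy table), counts
    content-word co-occurrences with a skip-n-gram moving-window model,
    and retrieves annotated text snippets by taxon or by dictionary-filtered
    word pair. Ships curated frugivory and pollination term dictionaries and
    a seeded synthetic-corpus generator with ground-truth manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stringi,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
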