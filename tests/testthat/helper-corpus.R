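# Build a corpus from in-memory strings by writing temp .txt files.
corpus_from_texts <- function(texts, min_word_chars = 5) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- vapply(seq_along(texts), function(i) {
    p <- file.path(dir, sprintf("mem%02d.txt", i))
    writeLines(texts[[i]], p, useBytes = TRUE)
    p
  }, character(1))
  load_corpus(paths, min_word_chars = min_word_chars)
}

ann_from_texts <- function(texts, tagger = NULL, min_word_chars = 5) {
  annotate_corpus(
    corpus_from_texts(texts, min_word_chars = min_word_chars),
    tagger = tagger
  )
}

# mock part-of-speech tagger honouring the plug-in contract: a lookup
# table with NOUN default for capitalized words and OTHER otherwise
mock_tagger <- function(lexicon) {
  force(lexicon)
  function(surfaces) {
    vapply(surfaces, function(s) {
      low <- tolower(s)
      if (!is.null(lexicon[[low]])) {
        lexicon[[low]]
      } else if (grepl("^[[:upper:]]", s)) "PROPN" else "OTHER"
    }, character(1), USE.NAMES = FALSE)
  }
}
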