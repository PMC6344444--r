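test_that("dictionary filtering keeps pairs with either member in the dictionary", {
  pairs <- tibble::tibble(
    term_a = c("eat", "eat", "wing"),
    term_b = c("fruit", "prey", "size"),
    count = c(5L, 3L, 2L), n_docs = c(1L, 1L, 1L)
  )
  kept <- filter_pairs_by_dictionary(pairs, load_dictionary("frugivory"))
  # "eat" is itself a dictionary term, so eat-prey stays: the user
  # disambiguates frugivory from predation
  expect_equal(kept$term_b, c("fruit", "prey"))
  # no member in the dictionary: dropped
  expect_false("size" %in% kept$term_b)
  # output is a subsequence of the input ranking
  expect_true(all(diff(match(
    paste(kept$term_a, kept$term_b),
    paste(pairs$term_a, pairs$term_b)
  )) > 0))
  # dictionary sharing no term with the table filters everything
  d <- withr::local_tempfile(fileext = ".txt")
  writeLines("pollen", d)
  expect_equal(nrow(filter_pairs_by_dictionary(pairs, load_dictionary(d))), 0)
})

test_that("byTaxa retrieval returns the sentences naming the queried taxon", {
  ann <- ann_from_texts(c(
    "Alouatta seniculus rests at dawn. Ateles paniscus eats ripe fruit there.",
    "Ateles paniscus crosses the canopy gap quickly."
  ))
  men <- find_names(ann)
  sn <- snippets_by_taxa(ann, men, "Ateles paniscus")
  expect_equal(nrow(sn), 2)
  expect_equal(sn$sent_index, c(2L, 1L))
  expect_true(all(vapply(
    sn$matched_names,
    function(m) "Ateles paniscus" %in% m$canonical, logical(1)
  )))
  # snippet ordering is (doc_id, sent_index)
  expect_true(all(diff(order(sn$doc_id, sn$sent_index)) > 0))
  # unknown names give an empty result, not an error
  expect_equal(nrow(snippets_by_taxa(ann, men, "Pan troglodytes")), 0)
  # genus-level queries match every congener mention
  genus <- snippets_by_taxa(ann, men, "Ateles")
  expect_equal(nrow(genus), 2)
})

test_that("snippet name spans are sound against the document text", {
  ann <- ann_from_texts(
    "Early filler words here. Alouatta seniculus and Ateles paniscus eat fruit."
  )
  men <- find_names(ann)
  sn <- snippets_by_taxa(ann, men, "Alouatta seniculus")
  doc_text <- ann$corpus$documents$text[1]
  nm <- sn$matched_names[[1]]
  for (r in seq_len(nrow(nm))) {
    expect_identical(substr(doc_text, nm$start[r], nm$end[r]), nm$verbatim[r])
    expect_true(nm$start[r] >= sn$start[1] && nm$end[r] <= sn$end[1])
  }
})

test_that("byKeywords retrieval matches the counting-window evidence exactly", {
  ann <- ann_from_texts(c(
    "Monkeys swallow seeds whole and later aid their dispersal widely.",
    "Seeds sprout. Dispersal happens elsewhere entirely."
  ))
  config <- cooccurrence_config(n = 6)
  sn <- snippets_by_pair(ann, c("swallow", "dispersal"), config)
  expect_equal(nrow(sn), 1)
  terms <- sn$matched_terms[[1]]
  expect_setequal(terms$term, c("swallow", "dispersal"))
  # spans are sound
  doc_text <- ann$corpus$documents$text[1]
  for (r in seq_len(nrow(terms))) {
    expect_identical(
      tolower(substr(doc_text, terms$start[r], terms$end[r])),
      terms$term[r]
    )
  }
  # terms in different sentences never co-occur
  expect_equal(nrow(snippets_by_pair(ann, c("sprout", "swallow"), config)), 0)
})

test_that("snippet occurrence totals equal the counted pair frequencies", {
  dir <- withr::local_tempdir()
  man <- generate_fixture_corpus(dir, n_docs = 2, sentences_per_doc = 9, seed = 17)
  ann <- annotate_corpus(load_corpus(man$paths))
  config <- cooccurrence_config(n = 6)
  pairs <- count_cooccurrences(ann, config)
  for (r in seq_len(min(nrow(pairs), 40))) {
    sn <- snippets_by_pair(ann, c(pairs$term_a[r], pairs$term_b[r]), config)
    expect_gt(nrow(sn), 0)
    expect_equal(sum(sn$n_occurrences), pairs$count[r],
      label = paste(pairs$term_a[r], pairs$term_b[r])
    )
  }
})

test_that("an exhaustive sentence scan finds the same byKeywords snippet set", {
  ann <- ann_from_texts(c(
    "Monkeys swallow seeds and aid dispersal. Seeds need monkeys.",
    "Dispersal of seeds by monkeys that swallow them whole is common."
  ))
  config <- cooccurrence_config(n = 4)
  pair <- c("seeds", "monkeys")
  sn <- snippets_by_pair(ann, pair, config)
  # oracle: for every sentence, check content positions directly
  expected_keys <- character(0)
  for (r in seq_len(nrow(ann$sentences))) {
    toks <- ann$tokens[
      ann$tokens$doc_id == ann$sentences$doc_id[r] &
        ann$tokens$sent_index == ann$sentences$sent_index[r] &
        ann$tokens$is_content, ,
    ]
    toks <- toks[order(toks$start), ]
    pa <- which(toks$norm == pair[1])
    pb <- which(toks$norm == pair[2])
    ok <- FALSE
    for (i in pa) for (j in pb) if (i != j && abs(j - i) <= config$n - 1) ok <- TRUE
    if (ok) {
      expected_keys <- c(expected_keys, paste(
        ann$sentences$doc_id[r], ann$sentences$sent_index[r]
      ))
    }
  }
  expect_setequal(paste(sn$doc_id, sn$sent_index), expected_keys)
})

test_that("snippets export as TSV and JSONL with stable field layout", {
  ann <- ann_from_texts(
    "Alouatta seniculus and Ateles paniscus swallow fruits aiding dispersal."
  )
  men <- find_names(ann)
  sn <- snippets_by_taxa(ann, men, "Alouatta seniculus", dict = "frugivory")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_snippets(sn, tsv, format = "tsv")
  back <- utils::read.delim(tsv)
  expect_equal(
    names(back),
    c("doc_id", "sent_index", "start", "end", "snippet",
      "matched_names", "matched_terms", "query")
  )
  expect_equal(back$matched_names, "Alouatta seniculus|Ateles paniscus")
  jl <- withr::local_tempfile(fileext = ".jsonl")
  export_snippets(sn, jl, format = "jsonl")
  rec <- jsonlite::fromJSON(readLines(jl)[1])
  expect_equal(rec$snippet, sn$text[1])
  expect_setequal(rec$matched_names, unique(sn$matched_names[[1]]$canonical))
  expect_setequal(rec$matched_terms, unique(sn$matched_terms[[1]]$term))
  # zero snippets export a header-only TSV
  empty_tsv <- withr::local_tempfile(fileext = ".tsv")
  export_snippets(sn[0, ], empty_tsv, format = "tsv")
  expect_equal(nrow(utils::read.delim(empty_tsv)), 0)
})

test_that("per-taxon co-occurrence tables only use the taxon's sentences", {
  ann <- ann_from_texts(c(
    "Ateles paniscus eats fruit slowly. Unrelated words follow here entirely."
  ))
  men <- find_names(ann)
  tab <- taxon_cooccurrences(ann, men, "Ateles paniscus")
  expect_true(nrow(lookup_pair(tab, "eats", "fruit")) == 1)
  expect_equal(nrow(lookup_pair(tab, "unrelated", "words")), 0)
})
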