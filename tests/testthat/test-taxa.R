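test_that("full binomials are recognized with canonical capitalization", {
  m <- find_scientific_names(
    "red boxes: Alouatta seniculus and Ateles paniscus eating"
  )
  expect_equal(nrow(m), 2)
  expect_equal(m$canonical, c("Alouatta seniculus", "Ateles paniscus"))
  expect_equal(m$rank_guess, rep("binomial", 2))
  expect_true(all(m$resolved))
})

test_that("abbreviated binomials are recognized verbatim", {
  m <- find_scientific_names("fruits of M. huberi were swallowed")
  expect_equal(nrow(m), 1)
  expect_equal(m$verbatim, "M. huberi")
  expect_equal(m$rank_guess, "abbreviated_binomial")
  expect_false(m$resolved)
})

test_that("blacklisted Latin phrases and months produce no mentions", {
  expect_equal(nrow(find_scientific_names("In situ observations at the site")), 0)
  expect_equal(nrow(find_scientific_names("samples taken in Ad hoc fashion")), 0)
  expect_equal(nrow(find_scientific_names("collected through May and June months")), 0)
  expect_equal(nrow(find_scientific_names("published by the University press office")), 0)
})

test_that("sentence-initial bigrams need a Latinate epithet ending", {
  expect_equal(nrow(find_scientific_names("The monkeys were seen eating.")), 0)
  expect_equal(nrow(find_scientific_names("Many observers were surprised.")), 0)
  # a real name opening a sentence still matches (epithet ends in -us)
  m <- find_scientific_names("Ateles paniscus was seen eating.")
  expect_equal(m$canonical, "Ateles paniscus")
  # mid-sentence candidates are not subject to the suffix guard
  m2 <- find_scientific_names("they followed Ateles belzebuth for days")
  expect_equal(m2$canonical, "Ateles belzebuth")
})

test_that("uninomials with rank suffixes are recognized", {
  m <- find_scientific_names("members of the Atelidae climbed while Rosaceae flowered")
  expect_equal(sort(m$canonical), c("Atelidae", "Rosaceae"))
  expect_equal(unique(m$rank_guess), "uninomial")
})

test_that("genus abbreviations resolve to the nearest preceding antecedent", {
  mk <- function(canonical, rank, sent) tibble::tibble(
    doc_id = "d", sent_index = sent, start = 1L, end = 10L,
    verbatim = canonical, canonical = canonical,
    rank_guess = rank, resolved = rank == "binomial"
  )
  # unique same-initial antecedent
  m <- resolve_abbreviations(dplyr::bind_rows(
    mk("Ficus insipida", "binomial", 1L),
    mk("F. insipida", "abbreviated_binomial", 5L)
  ))
  expect_equal(m$canonical[2], "Ficus insipida")
  expect_true(m$resolved[2])
  # no antecedent: canonical keeps the abbreviated form
  m2 <- resolve_abbreviations(mk("M. huberi", "abbreviated_binomial", 1L))
  expect_equal(m2$canonical, "M. huberi")
  expect_false(m2$resolved)
  # nearest-preceding rule, checked over every antecedent arrangement
  for (pos_ficus in 1:3) {
    rows <- list(
      mk("Fragaria vesca", "binomial", 4L),
      mk("F. vesca", "abbreviated_binomial", 6L)
    )
    rows <- append(rows, list(mk("Ficus insipida", "binomial", pos_ficus)), 0)
    m3 <- resolve_abbreviations(dplyr::bind_rows(rows))
    abbr <- m3[m3$rank_guess == "abbreviated_binomial", ]
    expect_equal(abbr$canonical, "Fragaria vesca") # Fragaria is always nearer
  }
  # with the full mention AFTER the abbreviation there is no antecedent
  m4 <- resolve_abbreviations(dplyr::bind_rows(
    mk("F. vesca", "abbreviated_binomial", 1L),
    mk("Fragaria vesca", "binomial", 3L)
  ))
  expect_false(m4$resolved[m4$rank_guess == "abbreviated_binomial"])
})

test_that("resolution never alters full binomial mentions", {
  ann <- ann_from_texts(
    "Ficus insipida fruits ripen. Fruits of F. insipida were eaten by birds."
  )
  men <- find_names(ann)
  bin <- men[men$rank_guess == "binomial", ]
  expect_equal(bin$canonical, "Ficus insipida")
  expect_true(all(men$resolved))
})

test_that("the taxon index maps names to their sentences, ranked by count", {
  ann <- ann_from_texts(c(
    "Ateles paniscus eats fruit. Other monkeys watch. Ateles paniscus returns.",
    "Alouatta seniculus sleeps near the river bank."
  ))
  men <- find_names(ann)
  idx <- build_taxon_index(men)
  expect_equal(idx$names$canonical[1], "Ateles paniscus")
  expect_equal(idx$names$n_snippets[1], 2)
  sites <- idx$names$sites[[1]]
  expect_equal(sites$sent_index, c(1L, 3L))
  # index soundness: every indexed sentence contains the name
  for (r in seq_len(nrow(idx$names))) {
    st <- idx$names$sites[[r]]
    for (k in seq_len(nrow(st))) {
      sent <- ann$sentences[
        ann$sentences$doc_id == st$doc_id[k] &
          ann$sentences$sent_index == st$sent_index[k],
      ]
      genus <- strsplit(idx$names$canonical[r], " ")[[1]][1]
      expect_match(sent$text, genus, fixed = TRUE)
    }
  }
  # empty input gives an empty index
  expect_equal(nrow(build_taxon_index(men[0, ])$names), 0)
})

test_that("higher ranks attach from a genus,family,class table", {
  ann <- ann_from_texts("Alouatta seniculus and Ateles paniscus forage together.")
  idx <- build_taxon_index(find_names(ann))
  tbl <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genus,family,class", "Alouatta,Atelidae,Mammalia"), tbl)
  idx <- attach_higher_ranks(idx, tbl)
  nm <- idx$names
  expect_equal(nm$family[nm$canonical == "Alouatta seniculus"], "Atelidae")
  expect_equal(nm$class[nm$canonical == "Alouatta seniculus"], "Mammalia")
  # absent genus stays unannotated without error
  expect_true(is.na(nm$family[nm$canonical == "Ateles paniscus"]))
  # header-only table leaves every genus unannotated
  tbl2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("genus,family,class", tbl2)
  idx2 <- attach_higher_ranks(build_taxon_index(find_names(ann)), tbl2)
  expect_true(all(is.na(idx2$names$family)))
})

test_that("malformed taxonomy tables report the offending line", {
  ann <- ann_from_texts("Alouatta seniculus rests.")
  idx <- build_taxon_index(find_names(ann))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genus,family,class", "Alouatta,Atelidae,Mammalia", "Oops,only-two"), bad)
  expect_error(attach_higher_ranks(idx, bad), "line 3")
  wrong_header <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g,f,c", "x,y,z"), wrong_header)
  expect_error(attach_higher_ranks(idx, wrong_header), "header")
})

test_that("every well-formed planted binomial is recovered (100% recall)", {
  dir <- withr::local_tempdir()
  man <- generate_fixture_corpus(dir, n_docs = 3, sentences_per_doc = 12, seed = 11)
  ann <- annotate_corpus(load_corpus(man$paths))
  men <- find_names(ann)
  for (doc in man$documents) {
    planted <- doc$planted[doc$planted$rank_guess == "binomial", ]
    for (r in seq_len(nrow(planted))) {
      hit <- men$doc_id == doc$doc_id &
        men$sent_index == planted$sent_index[r] &
        men$canonical == planted$expected_canonical[r]
      expect_true(any(hit), label = paste("planted", planted$expected_canonical[r]))
    }
  }
})

test_that("the negative-control corpus yields zero binomials", {
  dir <- withr::local_tempdir()
  man <- generate_fixture_corpus(dir,
    n_docs = 2, sentences_per_doc = 12,
    seed = 13, negative_control = TRUE
  )
  men <- find_names(annotate_corpus(load_corpus(man$paths)))
  expect_equal(sum(men$rank_guess == "binomial"), 0)
})

test_that("a custom recognizer can be plugged in", {
  stub <- function(sentence_text, doc_id, sent_index, offset, blacklist) {
    tibble::tibble(
      doc_id = doc_id, sent_index = sent_index,
      start = offset, end = offset + 3L,
      verbatim = "Stub", canonical = "Stubgenus stubspecies",
      rank_guess = "binomial", resolved = TRUE
    )
  }
  ann <- ann_from_texts("Any sentence at all works here.")
  men <- find_names(ann, recognizer = stub)
  expect_equal(unique(men$canonical), "Stubgenus stubspecies")
})
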