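# obsmine

`obsmine` is an R package for mining **sentence-level biodiversity
observations** — biotic interactions, functional traits, natural-history
notes — from a corpus of scientific literature. A large share of primary
biodiversity data is locked inside published articles stored as PDF
files; `obsmine` helps ecologists screen such a corpus quickly by turning
it into an indexed collection of one-sentence *snippets*, each anchored
either to a recognized **scientific name** or to a **word co-occurrence**
that matches a curated biodiversity dictionary (frugivory, pollination,
or any custom term list).

It is a headless library plus a small command-line tool: every step is a
plain function returning a tibble, so the pipeline fits scripted
screening workflows (e.g. candidate selection for meta-analyses, or
harvesting interaction records for databases like GloBI or TRY).

## Method

1. **Ingest & normalize.** Text is extracted from `.txt` and
   machine-readable `.pdf` files (files with no extractable text layer —
   typically scanned images — are flagged with a notification, never
   silently dropped). Publisher artifacts are repaired: line-break
   hyphenation (`disper-\nsal` → `dispersal`), typographic ligatures
   (`ﬁ` → `fi`), soft hyphens, whitespace.
2. **Annotate.** Documents are split into sentences (with guards for
   scholarly abbreviations, so `"M. huberi"` never splits a sentence) and
   tokens; content words (nouns, verbs, adjectives) are flagged, either by
   a pluggable part-of-speech tagger or by a deterministic stop-word rule.
3. **Recognize names.** A local rule-based recognizer finds Latin
   binomials (`Ateles paniscus`), abbreviated binomials (`A. paniscus`,
   resolved against the nearest preceding same-initial genus) and
   rank-suffixed uninomials (`Atelidae`), with a blacklist for Latin
   phrases and journal-title vocabulary that mimic the binomial shape.
   Optional higher ranks (family, class) attach from a local
   `genus,family,class` CSV.
4. **Count co-occurrences.** A **skip-n-gram** model slides a window of
   *n* content words (default *n* = 6) over each sentence; every unordered
   word pair at most *n* − 1 content positions apart counts one
   occurrence, pooled corpus-wide and ranked by frequency:
   for a sentence with content words *w*₁…*w*(_L_), the pair multiset is
   {{*w*ᵢ, *w*ⱼ} : 0 < *j* − *i* ≤ *n* − 1}.
5. **Retrieve snippets.** *byTaxa*: all sentences mentioning a queried
   taxon. *byKeywords*: all sentences where both members of a word pair
   co-occur within the counting window — so the snippet list is exactly
   the evidence behind the pair's count. Dictionaries filter the ranked
   pair table (a pair is kept when either member is a dictionary term;
   the user disambiguates, e.g. "eat + fruit" = frugivory vs
   "eat + prey" = predation).

A seeded synthetic-corpus generator (`generate_fixture_corpus()`) plants
invented-but-well-formed Latin names and interaction sentences and emits
a ground-truth manifest (including a brute-force-oracle co-occurrence
table), so the whole pipeline is testable offline.

## Worked example

```r
library(obsmine)

dir <- file.path(tempdir(), "demo")
man <- generate_fixture_corpus(dir, n_docs = 2, sentences_per_doc = 9, seed = 42)

corpus <- load_corpus(man$paths)
ann    <- annotate_corpus(corpus)
ann
#> <obs_annotations> 18 sentences, 248 tokens (108 content) across 2 documents

index <- build_taxon_index(find_names(ann))
index
#> <obs_taxon_index> 12 names
#> # A tibble: 10 x 3
#>    canonical                rank_guess n_snippets
#>  1 Arbofructus grandiflorus binomial            2
#>  2 Dulcifera maculatus      binomial            2
#>  ...

pairs <- count_cooccurrences(ann, cooccurrence_config(n = 6))
head(filter_pairs_by_dictionary(pairs, "frugivory"), 3)
#> # A tibble: 3 x 5
#>   term_a term_b    count n_docs doc_ids
#> 1 eaten  fruits        6      2 <chr [2]>
#> 2 eaten  pulp          6      2 <chr [2]>
#> 3 eaten  quickly       6      2 <chr [2]>

snippets_by_pair(ann, c("swallowed", "pulp"))[, c("doc_id", "sent_index", "text")]
#> # A tibble: 6 x 3
#>   doc_id sent_index text
#> 1 doc01           3 Fruits of Q. rubricata were swallowed whole and the pulp...
#> ...
```

Each index row says how many snippets mention a name (the two-snippet
names were re-mentioned as abbreviated genera and resolved); each pair
row is a pooled window count, and each retrieved snippet is one sentence
of evidence behind that count. `export_snippets()` and `export_pairs()`
write the results as TSV/JSONL.

## Command line

```sh
mine=$(Rscript -e 'cat(system.file("cli/mine.R", package = "obsmine"))')
Rscript $mine ingest  papers/*.pdf --out corpus.json
Rscript $mine names   corpus.json --taxonomy taxa.csv --out names.tsv
Rscript $mine cooccur corpus.json --window 6 --dict frugivory --out pairs.tsv
Rscript $mine snippets corpus.json --pair swallow,dispersal --out snippets.tsv
```

## Limitations

- Only embedded text layers are read; image-only PDFs are flagged for
  external OCR (an `ocr_hook` can be registered). Compressed PDF streams
  are treated as unreadable by the built-in extractor.
- The recognizer is deliberately biased toward false positives over
  false negatives; vernacular species names are not recognized.
- English prose is assumed; no lemmatization ("disperse" and "dispersal"
  are distinct terms, and dictionaries list inflected forms explicitly).
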