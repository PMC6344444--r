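---
title: "Mining biodiversity observation snippets from literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining biodiversity observation snippets from literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obsmine)
```

## The problem

Much primary biodiversity data — who eats whose fruit, which insect
visits which flower, trait values, natural-history notes — sits in prose
inside published articles, usually as PDF files. Screening hundreds of
such files by hand is the bottleneck of meta-analyses and of populating
interaction and trait databases. `obsmine` automates the mechanical part:
it turns a heterogeneous corpus into an indexed set of one-sentence
**snippets**, each a candidate biodiversity observation, retrievable
either by the scientific names it contains or by dictionary-filtered word
co-occurrences. The scientist stays in the loop: the tool surfaces and
ranks candidates, the user judges them.

## Pipeline and assumptions

### Ingestion and normalization

`load_corpus()` reads `.txt` and machine-readable `.pdf` files. The
built-in PDF reader extracts embedded text layers from uncompressed PDFs
(it is a matched counterpart of the fixture writer, not a general PDF
renderer); files whose extraction yields fewer than 20 word characters —
scanned image-only files, encrypted or compressed-stream files — are
flagged `readable = FALSE` with exactly one corpus notification each, and
excluded from all downstream steps. The threshold (parameter
`min_word_chars`, default 20) makes "machine-readable" an operational,
testable property; genuine articles have thousands of word characters, so
the default separates text layers from noise with a wide margin. An
`ocr_hook` (any function `path -> text`) can be registered to rescue
image-only files with an external OCR engine; none is bundled.

Normalization (`normalize_text()`) repairs what makes publisher PDFs
heterogeneous: line-break hyphenation is joined when the continuation
fragment is lowercase (a capitalized continuation, as in hyphenated
proper-name compounds, is left intact), ligature codepoints expand to
ASCII, soft hyphens disappear, and whitespace collapses — except that
runs containing two or more newlines are kept as `"\n\n"`, a paragraph
separator the sentence splitter treats as a hard boundary. The function
is total and idempotent, so re-normalizing stored text is always safe.
All character offsets downstream are 1-based and inclusive
(`substr(text, start, end)` recovers any span).

### Sentences, tokens, content words

The snippet unit is the sentence, so the splitter
(`split_sentences()`) is conservative: a boundary requires terminal
punctuation followed by whitespace and an uppercase letter or digit, and
is vetoed after single-letter abbreviations (so `"M. huberi"` survives
intact — essential, since abbreviated genus names look exactly like
sentence-ending initials), after scholarly abbreviations (`et al.`,
`Fig.`, `sp.`, `cf.`, ...), and inside parentheses. Tokens are maximal
alphanumeric runs with internal hyphens and apostrophes kept.

Content words gate the co-occurrence window. The package treats the
part-of-speech tagger as a plug-in (a function from token surfaces to
coarse tags, `NOUN`/`VERB`/`ADJ`/`PROPN`/other); with no tagger, a
deterministic fallback marks a token as content iff it is not in the
bundled stop-word list, has at least two characters, and is not purely
numeric. We chose the plug-in design over bundling a pretrained model
because it keeps the package fully deterministic and offline-testable; on
the clean prose of the fixtures both routes agree, and on real prose the
fallback errs toward admitting words (adverbs not in the stop list), which
at worst adds co-occurrence pairs a user can ignore. Proper nouns count
as nouns in the tagger route: scientific names are the very anchors of
the application. There is no lemmatization — "disperse" and "dispersal"
are distinct — because dictionary matching is defined on surface forms
and the bundled dictionaries list inflected forms explicitly.

### Scientific-name recognition

Name recognition is local and rule-based, mimicking the input/output
behavior of web name-finding services without the network dependency
(a `recognizer` plug-in can substitute an external service with the same
mention contract). Three shapes are matched, overlaps resolved
longest-first:

* **binomial**: capitalized Latin-compatible word (length ≥ 3) + lowercase
  word (length ≥ 3), neither blacklisted;
* **abbreviated binomial**: capital + period + lowercase epithet;
* **uninomial**: capitalized word with a rank suffix
  (`-idae`, `-aceae`, `-ales`, `-inae`).

Two guards suppress the known failure mode — Latin phrases and
journal-title vocabulary that mimic the binomial shape. A bundled
blacklist bars such words ("in situ", months, "Journal", "Biological",
...) from genus or epithet position, and a sentence-initial candidate
must carry a Latinate epithet ending (`-us`, `-a`, `-um`, `-is`,
`-ensis`, ...), which rejects ordinary "The monkeys"-style openings
without touching mid-sentence candidates. The design bias is deliberate:
false positives are cheap (the user sees an extra name), false negatives
are lost data, so every guard is narrow. Vernacular names are out of
scope.

Abbreviation resolution is per document and purely positional: an
abbreviated mention acquires the genus of the *nearest preceding* full
binomial or uninomial with the same initial. This matches how authors
introduce a species once and abbreviate thereafter; when no antecedent
exists the mention stays unresolved rather than guessing. Uninomials are
indexed as taxa too (a genus- or family-level snippet is still a usable
observation), and they participate as abbreviation antecedents.

Higher ranks (family, class) attach from a user-supplied
`genus,family,class` CSV — an offline stand-in for querying a taxonomic
web service, which keeps runs reproducible and corpus-private.

### The skip-n-gram co-occurrence model

A window of `n` content words slides over each sentence; the window
contributes the focus word paired with every other member, pooled
regardless of within-window distance. Counting is implemented
deterministically as: one occurrence per position pair `(i, j)` with
`i < j` and `j − i ≤ n − 1`. Randomly fixating a focus word, as the
model is sometimes described, yields the same pooled multiset; the
positional formulation is order-independent, oracle-checkable, and
O(nL) per sentence. The default `n = 6` reflects the span of a typical
verb phrase linking two entities in ecological prose ("X swallows the
ripe fruits of Y"); `n` is configurable (`cooccurrence_config()`), and
counts are monotone non-decreasing in `n`. Windows do not cross sentence
boundaries by default (the sentence is the snippet unit); a
`within_sentence = FALSE` switch exists for document-level
experimentation. Pairs are unordered (`term_a <= term_b`
lexicographically), pooled corpus-wide, ranked by count with alphabetical
tie-breaks, and carry the contributing document set for provenance.

### Dictionaries and retrieval

A biodiversity dictionary is a curated lowercase term list describing one
observation type. The bundled frugivory and pollination lists contain the
core descriptive vocabulary of those interactions plus explicit inflected
forms (no stemming); both files are versioned in their headers and custom
lists load from plain text. Dictionaries filter the *pair table*, not the
snippets: a pair is kept when **either** member is a dictionary term,
because single terms are genuinely informative ("swallow" and
"dispersal" each flag a candidate even when their partner term is not in
the list) and because the ambiguous cases ("eat + fruit" vs "eat + prey")
are exactly what the user should adjudicate.

Retrieval is two-mode. *byTaxa* returns every sentence whose mentions
include the queried canonical name (or genus). *byKeywords* returns every
sentence where both pair members occur as content words within the same
window constraint used for counting — deliberately stricter than mere
co-presence in a sentence, so that the retrieved snippet set is exactly
the evidence behind the pair's count (the per-snippet qualifying
position-pair counts sum to the pooled frequency; this identity is
enforced by tests). An experimental `taxon_cooccurrences()` ranks pairs
computed only over one taxon's sentences to characterize its semantic
context; with few sentences the ranking is noisy, hence the flag.

## The synthetic-corpus generator

`generate_fixture_corpus()` is first-class, tested code, and defines the
conditions under which the package's guarantees are demonstrated.
Documents are built from 3-sentence blocks — an interaction sentence
planting two full binomials (frugivory and pollination templates
alternate), a stop-word-rich filler sentence, and an abbreviated
re-mention of the block's first binomial — using an invented but
morphologically valid Latin lexicon (24 genera with distinct initials, 20
Latinate epithets). Invented names avoid encoding false biology about
real species in test data; distinct initials within a document make each
abbreviation's expected resolution unambiguous. A negative-control mode
emits prose made of blacklisted Latin phrases, months and journal-title
vocabulary with zero planted names. The PDF mode writes the same text
through the built-in PDF writer with injected line wraps, line-break
hyphenation and a ligature, exercising the full normalization path; an
optional zero-text-layer stub exercises the unreadable-file notification.

The manifest states the ground truth: every planted name with its
expected canonical form, per-sentence content streams computed by the
generator's own simple filter, and the expected co-occurrence table
computed by a brute-force all-pairs double loop — independent of the
windowed implementation it validates. All randomness flows through one
explicit seed (`withr::with_seed`), so regeneration is byte-identical.

What passing these fixtures does *not* show: recall on OCR-damaged or
typographically exotic real PDFs, recognition of names outside the
regular binomial shape (authorship strings, hybrids, "sp. nov."), or
dictionary coverage of real prose variation. The fixtures validate the
machinery exactly, not the linguistics broadly.

## Numerical and degenerate-input choices

* Offsets 1-based inclusive throughout; sentence indices 1-based.
* Ties in the pair ranking break alphabetically by (`term_a`, `term_b`);
  ties in the taxon index break alphabetically by canonical name.
* Empty documents, sentences without punctuation, tokens-only-punctuation
  sentences, header-only taxonomy tables and unknown taxon queries all
  return empty results rather than erroring; zero *readable* documents is
  the one hard error, since every downstream step would be vacuous.
* Identical repeated words pair with themselves once per position pair.
* Text decoding is fail-soft: invalid UTF-8 bytes become replacement
  characters, and a notification—not an exception—is the contract for
  unreadable files.
* Test and demonstration corpora are small (tens of sentences per
  document, a few documents per corpus); every quantity checked is exact
  integer arithmetic, so scale adds runtime, not information.

## Known limitations

* The built-in PDF reader handles uncompressed text streams (its writer's
  dialect and similar simple PDFs); compressed or encrypted files are
  reported unreadable rather than parsed. This is the designed division
  of labor: detection and notification are in scope, full PDF rendering
  and OCR are hooks.
* Column layouts, tables and reference sections of real PDFs are not
  specially handled; a references section will contribute sentences (and
  likely false-positive names from journal titles — partially mitigated
  by the blacklist).
* English-language assumptions sit in the stop-word list, the
  abbreviation guards and the Latinate-suffix heuristics.
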