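---
title: "Mining residue and point-mutation mentions with regular expressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining residue and point-mutation mentions with regular expressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(residuefinder)
```

## The mention model

A *residue mention* is a textual reference to one amino acid at one
sequence position ("Ser 56", "serine 56", "S56"); a *mutation mention*
additionally names the substituting acid, classically in wNm shorthand
("A64G").  Every extracted candidate is normalized to a
`residue_mention`: a one-letter wild-type code, the position kept as a
digit string, and an optional one-letter mutant code.  The canonical
rendering — `S56`, `A64G` — is the *key* used for counting and scoring.

```{r}
mention_key(normalize_mention("Ser", 56))
mention_key(normalize_mention("A", 64, "Gly"))
```

Two normalization choices deserve a note:

* **Positions are strings, not integers.** Sequence positions are labels;
  keeping them as digit strings avoids any integer-overflow ceiling and
  makes `0` and leading zeros (`S07`) invalid by form
  (`[1-9][0-9]*`) rather than by a range check.
* **Case policy.** One-letter codes must be uppercase, three-letter codes
  Title-case or all-caps (`Ser`, `SER`, never `sEr`), and full names are
  case-insensitive; `aspartate`/`glutamate` are accepted synonyms.  A
  lowercase `s56` is overwhelmingly a section label or variable name, not
  a serine.

## Library construction

Eight libraries ship, forming two lattices: breadth
(`mf` → `rf1` → `rf2` → `rf3`) and size (each `*_cut` keeps only the
expressions flagged as the productive core).

* `mf` holds the four wNm mutation patterns (one-letter and three-letter
  wild-type/mutant codes, no or one space) and requires a mutant token.
* `rf1` is `mf` with the mutant made optional: no-space residue forms.
* `rf2` adds a space between identifier and number plus full-name forms.
* `rf3` adds the permissive tail: a bare capital letter followed by a
  number (with or without a mutant tail), punctuation-junk separators for
  PDF conversion artifacts (`Ser*56`), arrow nomenclature (`A64→G`), and a
  large block of natural-language frames ("Ser56 was mutated to alanine",
  "substitution of Ser56 by Ala", …) built combinatorially from verbs,
  sentence frames and token forms.

The published full broad library comprises 1518 expressions and its cut
counterpart 6; the libraries here are reconstructed generatively in code
(the original distribution files are not shippable as package data) with
the combinatorics calibrated to those published sizes, and the structure
counts are enforced by tests through the pattern-file round trip:

```{r}
length(get_library("rf3"))
length(get_library("rf3_cut"))
```

Pattern files are plain text, one PCRE per line with named groups
`wt_res`, `pos` and optionally `mut_res`; `#` starts a comment, and a
trailing tab-separated `[CASE_SENSITIVE]` or `[CUT]` marker sets the entry
flags (entries are case-insensitive by default, the convention of the
field's mutation-mining pattern files, with `[CUT]` an extension of this
package).  `load_pattern_file()` validates each line and reports the line
number of anything that fails to compile or lacks a required group.

## Matching and collapsing

The matching semantics are *every expression anchored at every offset*:
a hit is recorded wherever some expression matches, overlapping hits
included.  The engine scans each expression over all documents with a
vectorized pass and only falls back to exhaustive offset enumeration for
the expression/document pairs that matched at all, which keeps the
common no-match case cheap across 1518 expressions.  The test suite pins
this behaviour to an independent brute-force oracle that literally tries
every expression at every offset.

Raw hits then pass through normalization (dropping candidates whose
tokens do not parse) and a collapse rule: **at each span start, the
longest parse survives**, with mutation parses preferred on length ties.
So `S56A` is one mutation mention, not a mutation plus an embedded
residue `S56`:

```{r}
extract_mentions("the S56A mutant", get_library("rf3"))$matches[
  , c("start", "end", "raw_text", "key")]
```

One consequence is worth stating plainly: growing the library is
monotone over *matches*, not over normalized keys.  Where a narrow
library reads `S275→A` only as the residue `S275`, the broad one parses
the whole mutation `S275A` — the match at that start survives and
lengthens, but its key changes.  The monotonicity properties in the test
suite are therefore phrased over span coverage.

`allow_single_digit` is applied as a post-filter on the position token.
Residue libraries default to accepting `G2`; the mutation-only `mf`
libraries default to rejecting single-digit positions, their historical
convention.  Known, deliberate trade-offs of the broad library include
the bare capital+number pattern matching phage and equipment names
("T7", "C18") and all-caps three-letter codes contributing a spurious
bare reading (`SER56` also exposing `R56` to the bare pattern at a later
offset); these are precision costs accepted in exchange for recall.

## Evaluation conventions

Scoring compares per-document extracted keys against a gold standard in
two modes: `single` (set semantics — each unique key counts once per
document) and `full` (multiset semantics — per key, TP gains the minimum
of extracted and gold counts, FP the extracted excess, FN the gold
excess).  Precision is `TP/(TP+FP)`, recall `TP/(TP+FN)`, and

$$F_\beta = \frac{(\beta^2 + 1)\,P\,R}{\beta^2 P + R}$$

reported by default for $\beta \in \{1, 2\}$; $\beta > 1$ weights recall,
which is usually the quantity to protect in literature mining — false
positives can be filtered by inspection, false negatives are simply
lost.  Report rows print ratios to three decimals, round-half-even.
Degenerate cases follow the usual conventions (nothing retrieved and
nothing expected scores precision 1; nothing expected scores recall 1).

`error_breakdown()` tallies analyst-assigned error causes.  A record may
carry several labels and then counts in each class, so percentages are
of total labelled *incidences*, which need not equal the number of
records.

## The synthetic corpus

Real annotated full-text corpora cannot ship with the package, so the
generator builds desk-scale stand-ins: filler prose (digit-free,
lowercase, incapable of matching anything) with planted mentions across
the eight nomenclature forms, classed distractor fragments drawn from the
observed false-positive families (motif names, equipment and substrates,
bibliography entries, protein names, short names, PDF artifacts, chemical
formulas), and an optional references tail.  The planted spans *are* the
gold standard.  Design constraints worth knowing:

* Everything derives from one seeded stream (`withr::with_seed`), so a
  configuration reproduces its corpus byte for byte and leaves the
  caller's RNG untouched.
* Mention positions are drawn from 10–400 (1–9 for the single-digit
  form), while numerals in bibliography and equipment distractors come
  from 600–999, so a distractor false positive can never collide with a
  gold key.
* Each bibliography includes one citation line guaranteed to produce a
  broad-library false positive, making bibliography stripping measurable:
  stripping changes FP and never TP or FN on these corpora.
* The default form mix (weights leaning on no-space one-letter forms,
  every variant present) is an arbitrary but fixed study condition, not a
  fit to any measured distribution.

What these corpora show is *mechanism*: that a library recovers exactly
the forms it covers (recall 1.0 on covered-form corpora, 0.0 for `rf1` on
spaced-only text), that the precision ordering of the libraries behaves
as designed, and that stripping bibliographies trims false positives.
What they cannot show is real-text performance — filler prose is far
cleaner than converted PDFs, so absolute precision figures on synthetic
corpora do not transfer to articles.

```{r}
corpus <- generate_corpus(corpus_config(n_docs = 20, seed = 7))
score_extraction(extract_corpus(corpus$documents, get_library("rf3_cut")),
                 corpus$gold, mode = "full")
```

## Problem sizes and cost

The cut libraries exist because scan cost is linear in the number of
expressions: 1518 versus 6 expressions is a 253-fold difference in
patterns applied per document.  At desk scale, the broad library
processes a few hundred synthetic documents in seconds and the cut
library the same corpus in a small fraction of that; the suite-level
property runs use 1000 documents.

## Known limitations

* The libraries are generative reconstructions calibrated to published
  entry counts, not byte copies of any distributed pattern files.
* The natural-language frame block covers common mutation phrasings but
  is necessarily finite; phrasings outside it are missed (the dominant
  causes of false negatives in practice are text embedded in figures and
  phrasings without a matching expression).
* Bibliography detection requires a heading alone on a line in the final
  half of the document; reference lists without such a heading are not
  stripped.
* Mentions are not grounded to protein sequences or databases; mapping
  keys such as `A64G` onto specific proteins is out of scope.
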