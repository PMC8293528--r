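# residuefinder

Regular-expression mining of amino acid residue and point-mutation
mentions in biomedical text.

Statements about individual protein residues — "Ser 56 is phosphorylated",
"the A64G mutant" — carry much of the mechanistic content of the
structure–function literature, yet they are written in many competing
nomenclatures: one-letter and three-letter codes with or without a space,
full amino-acid names, wNm mutation shorthand (`A64G` = alanine 64 replaced
by glycine), arrow notation (`A64→G`), and phrasings such as "Ser56 was
mutated to alanine".  `residuefinder` extracts these mentions with
selectable regular-expression libraries, normalizes them to canonical keys
(`S56`, `A64G`), and scores extraction runs against gold-standard
annotations with precision, recall and

```
F_β = ((β² + 1) · P · R) / (β² · P + R)
```

where `β > 1` weights recall more heavily (`β = 0` reduces to precision).

## The libraries

| name | expressions | covers |
|---|---|---|
| `mf` / `mf_cut` | 4 / 2 | wNm point mutations only |
| `rf1` / `rf1_cut` | 4 / 3 | + plain residues, no-space forms |
| `rf2` / `rf2_cut` | 8 / 6 | + spaced and full-name forms |
| `rf3` / `rf3_cut` | 1518 / 6 | + bare capital+number, arrows, PDF artifacts, natural-language phrasings |

The broad `rf3` library trades precision for recall; each `*_cut` variant
keeps only the most productive expressions, cutting scan cost by orders of
magnitude (1518 → 6 expressions for `rf3`) at a small recall cost.
Libraries nest by construction (`rf1 ⊆ rf2 ⊆ rf3`, cut ⊆ full), and custom
libraries can be loaded from plain-text pattern files
(`load_pattern_file()`), one PCRE per line with named groups `wt_res`,
`pos` and optionally `mut_res`.

## Worked example

```r
library(residuefinder)

text <- "Mutation of Ser 56 to alanine (S56A) slowed inactivation, unlike the A64G mutant."
result <- extract_mentions(text, get_library("rf3"))
result$matches[, c("start", "end", "raw_text", "key")]
#>   start end raw_text  key
#> 1    12  18   Ser 56  S56
#> 2    31  35     S56A S56A
#> 3    69  73     A64G A64G
```

Spans are 0-based half-open character offsets; overlapping parses at the
same start collapse to the longest one, so `S56A` is reported once as a
mutation rather than additionally as the residue `S56`.

Evaluation against a gold standard, here on a generated synthetic corpus
whose planted mentions are the gold standard:

```r
corpus <- generate_corpus(corpus_config(n_docs = 20, seed = 7))
extracted <- extract_corpus(corpus$documents, get_library("rf3_cut"))
score_extraction(extracted, corpus$gold, mode = "full")
#> <eval_result> TP=91 FP=75 FN=7
#>   precision 0.548  recall 0.929  F1 0.689  F2 0.815
```

Passing `strip_bib = TRUE` to the extraction removes reference lists
(which yield almost no true mentions) before matching, and
`mode = "single"` scores each unique mention once per document instead of
per occurrence.

## Command line

The installed `residuefinder` executable exposes the same pipeline:

```sh
residuefinder generate --out corpus/ --seed 7 --n-docs 20
residuefinder extract --library rf3_cut --count full --out extracted.tsv corpus/
residuefinder evaluate --extracted extracted.tsv --gold corpus/gold.tsv --count full
residuefinder libraries
```

## Documentation

See the methods vignette (`vignettes/residue-mention-mining.Rmd`) for the
mention model, library construction, matching and collapsing semantics,
the evaluation conventions and the synthetic corpus design, including
known limitations.
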