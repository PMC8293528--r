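# Synthetic corpus generator: determinism, planting fidelity, recall
# recovery and the bibliography invariant.

test_that("identical configurations reproduce the corpus byte for byte", {
  cfg <- corpus_config(n_docs = 6, seed = 33)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  # a different seed changes the text
  c3 <- generate_corpus(corpus_config(n_docs = 6, seed = 34))
  expect_false(identical(c1$documents[[1]]$text, c3$documents[[1]]$text))
  # generation leaves the caller's RNG stream untouched
  set.seed(9)
  before <- runif(1)
  set.seed(9)
  invisible(generate_corpus(cfg))
  expect_identical(runif(1), before)
})

test_that("plant_form renders each nomenclature and rejects mismatches", {
  res <- normalize_mention("S", 56)
  mut <- normalize_mention("A", 64, "G")
  expect_equal(plant_form(res, "one_nospace"), "S56")
  expect_equal(plant_form(res, "three_space"), "Ser 56")
  expect_equal(plant_form(res, "full_name"), "serine 56")
  expect_equal(plant_form(mut, "wnm"), "A64G")
  expect_equal(plant_form(mut, "arrow"), "A64→G")
  expect_equal(plant_form(normalize_mention("G", 2), "single_digit"), "G2")
  expect_error(plant_form(res, "wnm"), "mutation")
  expect_error(plant_form(mut, "three_nospace"), "plain residue")
  expect_error(plant_form(res, "single_digit"), "1-9")
  expect_error(plant_form(res, "no_such_form"), "unknown form")
})

test_that("planted spans re-extract to their ledger keys under rf3", {
  corpus <- generate_corpus(corpus_config(n_docs = 10, seed = 7))
  rf3 <- get_library("rf3")
  led <- corpus$mention_ledger
  for (i in seq_len(nrow(led))) {
    frag <- substr(corpus$documents[[led$doc_id[i]]]$text,
                   led$start[i] + 1L, led$end[i])
    got <- extract_mentions(frag, rf3)$unique_mentions
    expect_equal(got, led$key[i], info = frag)
  }
})

test_that("each library attains recall 1 on its covered-form corpora", {
  for (name in c("mf", "rf1", "rf2", "rf3", "rf3_cut")) {
    corpus <- covered_corpus(name, n_docs = 10, seed = 101)
    results <- extract_corpus(corpus$documents, get_library(name))
    r <- score_extraction(results, corpus$gold, mode = "full")
    expect_equal(r$recall, 1, info = name)
  }
})

test_that("the narrow library has recall 0 on spaced-form-only corpora", {
  corpus <- generate_corpus(corpus_config(
    n_docs = 10, seed = 55,
    form_mix = c(one_space = 1, three_space = 1, full_name = 1),
    distractors_per_doc = c(0L, 0L),
    include_bibliography = FALSE
  ))
  results <- extract_corpus(corpus$documents, get_library("rf1"))
  r <- score_extraction(results, corpus$gold, mode = "full")
  expect_equal(r$recall, 0)
  expect_equal(r$tp, 0L)
})

test_that("stripping bibliographies removes false positives, never hits", {
  corpus <- generate_corpus(corpus_config(n_docs = 15, seed = 21))
  rf3 <- get_library("rf3")
  kept <- extract_corpus(corpus$documents, rf3)
  stripped <- extract_corpus(corpus$documents, rf3, strip_bib = TRUE)
  r_kept <- score_extraction(kept, corpus$gold, mode = "full")
  r_stripped <- score_extraction(stripped, corpus$gold, mode = "full")
  expect_equal(r_stripped$tp, r_kept$tp)
  expect_equal(r_stripped$fn, r_kept$fn)
  expect_lt(r_stripped$fp, r_kept$fp)
})

test_that("gold counts equal the planted-mention ledger", {
  corpus <- generate_corpus(corpus_config(n_docs = 12, seed = 88))
  led <- corpus$mention_ledger
  for (id in names(corpus$gold$docs)) {
    g <- corpus$gold$docs[[id]]
    planted <- table(led$key[led$doc_id == id])
    expect_equal(sort(names(g)), sort(names(planted)))
    expect_equal(as.integer(g[names(planted)]), as.integer(planted))
  }
  # section map covers the document contiguously
  for (doc in corpus$documents) {
    sm <- doc$section_map
    expect_equal(sm$start[1], 0L)
    expect_equal(sm$end[nrow(sm)], nchar(doc$text))
    expect_true(all(sm$start[-1] >= sm$end[-nrow(sm)]))
  }
})

test_that("degenerate configurations are rejected up front", {
  expect_error(corpus_config(form_mix = c(one_nospace = 0)), "positive weight")
  expect_error(corpus_config(form_mix = c(bogus_form = 1)), "unknown form")
  expect_error(corpus_config(distractor_mix = c(bogus = 1)), "unknown distractor")
  expect_error(corpus_config(mentions_per_doc = c(5L, 2L)))
  expect_error(corpus_config(form_mix = c(one_nospace = -1)), "non-negative")
})

test_that("written corpora round-trip through the readers", {
  corpus <- generate_corpus(corpus_config(n_docs = 4, seed = 3))
  dir <- withr::local_tempdir()
  write_synthetic_corpus(corpus, dir)
  docs <- read_documents(dir)
  expect_setequal(names(docs), names(corpus$documents))
  for (id in names(docs)) {
    expect_equal(docs[[id]]$text, corpus$documents[[id]]$text)
  }
  gold <- read_gold(file.path(dir, "gold.tsv"))
  expect_equal(gold$docs[names(corpus$gold$docs)], corpus$gold$docs)
})
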