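# Extraction semantics: nomenclature coverage, spans, collapsing,
# single-digit handling, bibliography stripping and counting modes.

test_that("the library tiers cover their advertised nomenclatures", {
  rf1 <- get_library("rf1")
  rf2 <- get_library("rf2")
  rf3 <- get_library("rf3")
  expect_equal(extract_mentions("the A64G mutant", rf1)$unique_mentions, "A64G")
  # spaced form: invisible to rf1, found from rf2 on
  expect_equal(length(extract_mentions("Ser 56 is phosphorylated", rf1)$unique_mentions), 0L)
  expect_equal(extract_mentions("Ser 56 is phosphorylated", rf2)$unique_mentions, "S56")
  expect_equal(extract_mentions("Ser 56 is phosphorylated", rf3)$unique_mentions, "S56")
  # the bare capital+number allowance fires on phage names (by design)
  expect_equal(extract_mentions("Bacteriophage T7 polymerase", rf3)$unique_mentions, "T7")
  # full names, arrows, PDF junk
  expect_equal(extract_mentions("mutated at serine 56", rf3)$unique_mentions, "S56")
  expect_equal(extract_mentions("the A64→G channel", rf3)$unique_mentions, "A64G")
  expect_equal(extract_mentions("a Ser*56 artifact", rf3)$unique_mentions, "S56")
})

test_that("single-digit positions are a switchable acceptance", {
  rf1 <- get_library("rf1")
  expect_equal(extract_mentions("residue G2", rf1,
                                allow_single_digit = TRUE)$unique_mentions, "G2")
  expect_equal(length(extract_mentions("residue G2", rf1,
                                       allow_single_digit = FALSE)$unique_mentions), 0L)
  # the mutation-only library defaults to multi-digit positions
  expect_equal(length(extract_mentions("the A6G mutant",
                                       get_library("mf"))$unique_mentions), 0L)
  expect_equal(extract_mentions("the A64G mutant",
                                get_library("mf"))$unique_mentions, "A64G")
})

test_that("spans are 0-based half-open and raw_text slices the document", {
  text <- "xx Ser 56 yy A64G zz"
  m <- extract_mentions(text, get_library("rf2"))$matches
  expect_equal(m$start, c(3L, 13L))
  expect_equal(m$end, c(9L, 17L))
  for (i in seq_len(nrow(m))) {
    expect_equal(substr(text, m$start[i] + 1L, m$end[i]), m$raw_text[i])
  }
  expect_true(all(diff(m$start) > 0))
})

test_that("a wNm mutation is reported once, not also as its embedded residue", {
  r <- extract_mentions("the S56A mutant", get_library("rf3"))
  expect_equal(r$unique_mentions, "S56A")
  expect_equal(nrow(r$matches), 1L)
})

test_that("unmatchable and degenerate positions never surface", {
  rf3 <- get_library("rf3")
  expect_equal(length(extract_mentions("sample S07 and S0 here", rf3)$unique_mentions), 0L)
  expect_equal(length(extract_mentions("", rf3)$unique_mentions), 0L)
  expect_equal(length(extract_mentions("no mentions at all", rf3)$unique_mentions), 0L)
})

test_that("count_mentions distinguishes unique-mention and full-count modes", {
  r <- extract_mentions("S56 then S56 then A64G", get_library("rf1"))
  expect_equal(count_mentions(r, "single"), c(S56 = 1L, A64G = 1L))
  expect_equal(count_mentions(r, "full"), c(S56 = 2L, A64G = 1L))
  empty <- extract_mentions("nothing", get_library("rf1"))
  expect_equal(length(count_mentions(empty, "single")), 0L)
  expect_equal(length(count_mentions(empty, "full")), 0L)
  # full-mode counts dominate single-mode counts key-wise
  full <- count_mentions(r, "full")
  single <- count_mentions(r, "single")
  expect_true(all(full[names(single)] >= single))
})

test_that("bibliography stripping follows the heading and half-text rules", {
  body <- paste(rep("filler prose sentence here.", 20), collapse = " ")
  tail <- "\nReferences\n1. Smith et al. Proc Natl Acad Sci U S A 700: 1-10."
  stripped <- strip_bibliography(paste0(body, tail))
  expect_equal(stripped, paste0(body, "\n"))
  # no heading: unchanged
  expect_equal(strip_bibliography(body), body)
  # heading in the first half: unchanged
  early <- paste0("Intro.\nReferences\n", body, body)
  expect_equal(strip_bibliography(early), early)
  # heading must sit alone on its line
  inline <- paste0(body, " see References for details ", body)
  expect_equal(strip_bibliography(inline), inline)
  # document form records the removed range
  doc <- strip_bibliography(document("d", paste0(body, tail)))
  expect_equal(doc$section_map$section, "bibliography")
  expect_equal(doc$section_map$start, nchar(body) + 1L)  # after the "\n"
  expect_equal(doc$text, paste0(body, "\n"))
})

test_that("abstract-only extraction is a subset of full-text extraction", {
  corpus <- generate_corpus(corpus_config(n_docs = 8, seed = 19))
  full <- extract_corpus(corpus$documents, get_library("rf2"))
  abst <- extract_corpus(corpus$documents, get_library("rf2"),
                         abstract_only = TRUE)
  for (id in names(full)) {
    expect_true(all(abst[[id]]$unique_mentions %in% full[[id]]$unique_mentions))
  }
})

test_that("library growth never removes matches on synthetic documents", {
  corpus <- generate_corpus(corpus_config(n_docs = 25, seed = 5))
  runs <- lapply(c("rf1", "rf2", "rf3"), function(name) {
    extract_corpus(corpus$documents, get_library(name))
  })
  for (id in names(corpus$documents)) {
    for (step in 1:2) {
      nm <- runs[[step]][[id]]$matches
      bm <- runs[[step + 1L]][[id]]$matches
      idx <- match(nm$start, bm$start)
      # every matched start survives; the broader library may extend the
      # span there (e.g. reading a residue as part of a full mutation)
      expect_false(anyNA(idx))
      expect_true(all(bm$end[idx] >= nm$end))
    }
  }
})

test_that("extraction agrees with the per-offset brute-force oracle", {
  texts <- c(
    "the A64G mutant of Ser 56",
    "S56 then S56 and serine 7 tails",
    "A1A2A3 overlap stress",
    "SER56 and the S4-S5 linker of T7",
    "substitution of Ser56 by Ala, and G2 was mutated to V",
    "a Ser*56 artifact near A64→G",
    "Asp 90 aspartic acid 12 glutamate 7",
    "no mentions in this one"
  )
  for (libname in c("rf2", "rf3_cut")) {
    lib <- get_library(libname)
    for (text in texts) {
      got <- extract_mentions(text, lib)$matches[, c("start", "end", "key")]
      want <- oracle_extract(text, lib)
      expect_equal(got, want, info = paste(libname, text))
    }
  }
  mini <- mini_library()
  for (text in texts) {
    got <- extract_mentions(text, mini)$matches[, c("start", "end", "key")]
    expect_equal(got, oracle_extract(text, mini), info = text)
  }
})

test_that("document I/O round-trips corpus files with escapes", {
  docs <- list(
    document("a", "line one\nline two\twith tab"),
    document("b", "backslash \\ and more"),
    document("c", "S56 mention")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus_file(docs, path)
  back <- read_documents(path)
  expect_equal(names(back), c("a", "b", "c"))
  for (id in names(back)) {
    expect_equal(back[[id]]$text, docs[[match(id, c("a", "b", "c"))]]$text)
  }
})
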