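# Scoring arithmetic, F-beta behaviour and error-cause summaries.

test_that("precision and recall follow their defining ratios", {
  expect_equal(precision_recall(66, 3, 102),
               c(precision = 66 / 69, recall = 66 / 168))
  expect_equal(precision_recall(385, 602, 23),
               c(precision = 385 / 987, recall = 385 / 408))
  expect_equal(unname(precision_recall(0, 0, 0)), c(1, 1))
  expect_equal(unname(precision_recall(0, 0, 5)), c(0, 0))
  expect_equal(unname(precision_recall(0, 4, 0)), c(0, 1))
  expect_error(precision_recall(-1, 0, 0), "non-negative")
})

test_that("f_beta interpolates between precision and recall", {
  # beta = 0 reduces to precision
  expect_equal(f_beta(0.8, 0.3, beta = 0), 0.8)
  # beta -> infinity tends to recall
  for (p in c(0.2, 0.7, 1)) {
    for (r in c(0.1, 0.5, 0.9)) {
      expect_lt(abs(f_beta(p, r, beta = 1e6) - r), 1e-9)
    }
  }
  # symmetric at beta = 1: F1(p, r) == F1(r, p), and F1(x, x) == x
  expect_equal(f_beta(0.3, 0.9), f_beta(0.9, 0.3))
  expect_equal(f_beta(0.6, 0.6), 0.6)
  # monotone in both arguments
  expect_lt(f_beta(0.4, 0.5, 2), f_beta(0.5, 0.5, 2))
  expect_lt(f_beta(0.5, 0.4, 2), f_beta(0.5, 0.5, 2))
  # zero denominator yields 0, not NaN
  expect_equal(f_beta(0, 0, 1), 0)
  expect_error(f_beta(0.5, 0.5, beta = -1), "non-negative")
  expect_error(f_beta(1.2, 0.5), "0, 1")
})

test_that("single-count scoring matches set semantics per document", {
  gold <- gold_standard(list(
    d1 = c(A64G = 1L, S56 = 1L),
    d2 = c(G2 = 1L),
    d3 = integer(0)
  ))
  extracted <- list(
    d1 = c(A64G = 1L, T7 = 1L),   # one hit, one spurious, one miss
    d2 = c(G2 = 3L),              # multiplicity ignored in single mode
    d4 = c(S99 = 1L)              # document absent from gold
  )
  r <- score_extraction(extracted, gold, mode = "single")
  expect_equal(c(r$tp, r$fp, r$fn), c(2L, 2L, 1L))
  o <- oracle_score(extracted, gold$docs, mode = "single")
  expect_equal(list(r$tp, r$fp, r$fn), list(o$tp, o$fp, o$fn))
})

test_that("full-count scoring matches multiset semantics per key", {
  gold <- gold_standard(list(d1 = c(S56 = 1L)))
  r <- score_extraction(list(d1 = c(S56 = 3L)), gold, mode = "full")
  expect_equal(c(r$tp, r$fp, r$fn), c(1L, 2L, 0L))
  gold2 <- gold_standard(list(d1 = c(S56 = 3L, A64G = 2L)))
  r2 <- score_extraction(list(d1 = c(S56 = 1L, T7 = 1L)), gold2, mode = "full")
  expect_equal(c(r2$tp, r2$fp, r2$fn), c(1L, 1L, 4L))
  o2 <- oracle_score(list(d1 = c(S56 = 1L, T7 = 1L)), gold2$docs, mode = "full")
  expect_equal(list(r2$tp, r2$fp, r2$fn), list(o2$tp, o2$fp, o2$fn))
})

test_that("swapping extraction and gold swaps FP with FN", {
  a <- list(d1 = c(S56 = 2L, A64G = 1L), d2 = c(G7 = 1L))
  b <- list(d1 = c(S56 = 1L, T9 = 1L), d2 = integer(0))
  for (mode in c("single", "full")) {
    fwd <- score_extraction(a, gold_standard(b), mode = mode)
    rev <- score_extraction(b, gold_standard(a), mode = mode)
    expect_equal(fwd$tp, rev$tp)
    expect_equal(fwd$fp, rev$fn)
    expect_equal(fwd$fn, rev$fp)
  }
})

test_that("scoring agrees with the greedy multiset oracle on random pairs", {
  withr::with_seed(2024, {
    keys <- c("S56", "A64G", "G2", "T77", "W9", "K123R")
    for (trial in 1:40) {
      rand_docs <- function() {
        ids <- sample(c("a", "b", "c"), sample(1:3, 1))
        out <- lapply(ids, function(id) {
          k <- sample(keys, sample(0:4, 1))
          if (length(k) == 0L) return(integer(0))
          structure(sample(1:3, length(k), replace = TRUE), names = k)
        })
        names(out) <- ids
        out
      }
      e <- rand_docs()
      g <- rand_docs()
      for (mode in c("single", "full")) {
        got <- score_extraction(e, gold_standard(g), mode = mode)
        want <- oracle_score(e, g, mode = mode)
        expect_equal(list(got$tp, got$fp, got$fn),
                     list(want$tp, want$fp, want$fn))
      }
    }
  })
})

test_that("report rows carry counts and three-decimal ratios", {
  r <- new_eval_result(66, 3, 102, beta = c(1, 2))
  row <- format_eval_report(r, label = "demo")
  expect_equal(row, "demo\t66\t3\t102\t0.957\t0.393\t0.557\t0.445")
  expect_equal(names(r$f_scores), c("1", "2"))
})

test_that("error_breakdown reports percentages of labelled incidences", {
  fn <- error_breakdown(c(in_image = 15, regex_not_found = 7), type = "fn")
  expect_equal(fn$count, c(15, 7))
  expect_equal(round(fn$percent, 1), c(68.2, 31.8))
  # list-of-labels input; a record with two labels counts in both classes
  fp <- error_breakdown(list(c("motif_name"), c("motif_name", "short_name"),
                             c("pdf_artifact")), type = "fp")
  expect_equal(fp$class, c("motif_name", "short_name", "pdf_artifact"))
  expect_equal(fp$count, c(2, 1, 1))
  expect_equal(sum(fp$percent), 100)
  expect_error(error_breakdown(c(nonsense = 2), type = "fp"), "unknown")
  expect_equal(nrow(error_breakdown(integer(0), type = "fn")), 0L)
})

test_that("gold standards validate their keys and round-trip through files", {
  expect_error(gold_standard(list(d1 = c(s56 = 1))), "invalid gold key")
  g <- gold_standard(list(doc1 = c(S56 = 2L, A64G = 1L), doc2 = integer(0)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gold(g, path)
  back <- read_gold(path)
  expect_equal(back$docs, g$docs)
})
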