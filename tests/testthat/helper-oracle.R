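# Independent oracles used across the suite.
#
# oracle_extract(): brute-force matcher that tries every library expression
# anchored at every character offset (so overlapping hits of one pattern
# are found by construction), then applies the definitional collapse rule.
# It shares only the nomenclature table with the extractor, not its
# scanning strategy.
oracle_extract <- function(text, library, allow_single_digit = TRUE) {
  entries <- library$entries
  n <- nchar(text)
  rows <- list()
  for (j in seq_len(nrow(entries))) {
    pat <- entries$expression[j]
    if (!entries$case_sensitive[j]) pat <- paste0("(?i)", pat)
    for (off0 in 0:(max(n - 1L, 0L))) {
      probe <- sprintf("(?s)^.{%d}((?:%s))", off0, pat)
      m <- regexpr(probe, text, perl = TRUE)
      if (m[1] == -1L) next
      cs <- attr(m, "capture.start")[1L, ]
      cl <- attr(m, "capture.length")[1L, ]
      nm <- attr(m, "capture.names")
      w <- which(nm == "")[1L]
      len <- cl[[w]]
      if (len <= 0L) next
      tok <- function(g) {
        idx <- which(nm == g)
        if (length(idx) == 0L || cs[[idx[1]]] == -1L || cl[[idx[1]]] == 0L) {
          return(NA_character_)
        }
        substr(text, cs[[idx[1]]], cs[[idx[1]]] + cl[[idx[1]]] - 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = off0, end = off0 + len,
        wt_token = tok("wt_res"), pos_token = tok("pos"),
        mut_token = tok("mut_res"), pattern_idx = j,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      key = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  # normalize; drop non-parsing candidates
  wt <- vapply(df$wt_token, function(x) {
    out <- tryCatch(to_one_letter(x), error = function(e) NA_character_)
    out
  }, character(1), USE.NAMES = FALSE)
  mut <- vapply(df$mut_token, function(x) {
    if (is.na(x)) return(NA_character_)
    tryCatch(to_one_letter(x), error = function(e) "!")
  }, character(1), USE.NAMES = FALSE)
  ok <- !is.na(wt) & grepl("^[1-9][0-9]*$", df$pos_token) &
    (is.na(mut) | mut != "!")
  if (!allow_single_digit) ok <- ok & nchar(df$pos_token) > 1L
  df <- df[ok, , drop = FALSE]
  wt <- wt[ok]; mut <- mut[ok]
  if (nrow(df) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      key = character(0), stringsAsFactors = FALSE))
  }
  df$key <- paste0(wt, df$pos_token, ifelse(is.na(mut), "", mut))
  df$has_mut <- !is.na(mut)
  # collapse: one survivor per span start -- longest, mutation preferred,
  # then library order
  df <- df[order(df$start, -df$end, !df$has_mut, df$pattern_idx), , drop = FALSE]
  df <- df[!duplicated(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("start", "end", "key")]
}

# Multiset/set scoring oracle: expands per-document counts into explicit
# occurrence lists and matches them greedily one occurrence at a time.
oracle_score <- function(extracted, gold_docs, mode = c("single", "full")) {
  mode <- match.arg(mode)
  expand <- function(x) {
    if (is.null(x) || length(x) == 0L) return(character(0))
    if (mode == "single") unique(names(x)) else rep(names(x), x)
  }
  tp <- fp <- fn <- 0L
  for (id in union(names(extracted), names(gold_docs))) {
    ev <- expand(extracted[[id]])
    gv <- expand(gold_docs[[id]])
    for (k in ev) {
      hit <- match(k, gv)
      if (!is.na(hit)) {
        tp <- tp + 1L
        gv <- gv[-hit]
      } else {
        fp <- fp + 1L
      }
    }
    fn <- fn + length(gv)
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Small custom library exercising every structural pattern family (core,
# bare, junk, arrow, phrase frames) for oracle comparisons.
mini_library <- function() {
  lib <- get_library("rf3")
  keep <- c("res_one_nospace", "res_one_space", "res_three_nospace",
            "res_three_space", "res_full_nospace", "res_full_space",
            "x_bare", "x_bare_mut", "x_junk_one", "x_junk_three",
            "x_arrow_one", "nl_mut_v1f01_one_one", "nl_mut_v2f09_three_one",
            "nl_res_f01_one")
  lib$entries <- lib$entries[lib$entries$pattern_id %in% keep, , drop = FALSE]
  rownames(lib$entries) <- NULL
  lib$name <- "mini"
  lib
}

# Corpus restricted to the forms a library is guaranteed to recover.
covered_corpus <- function(lib_name, n_docs = 15, seed = 101) {
  forms <- covered_forms(lib_name)
  generate_corpus(corpus_config(
    n_docs = n_docs, seed = seed,
    form_mix = structure(rep(1, length(forms)), names = forms),
    distractors_per_doc = c(0L, 0L),
    include_bibliography = FALSE
  ))
}

extraction_keys <- function(results) {
  lapply(results, `[[`, "unique_mentions")
}
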