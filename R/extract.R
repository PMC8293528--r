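# Match engine: applies a pattern library to document text, parses named
# capture groups into normalized mentions, and collapses overlapping hits.
#
# Matching semantics are "every pattern anchored at every offset": a hit is
# reported wherever some pattern matches, even when hits of the same
# pattern overlap.  The engine first runs a vectorized scan per pattern
# (non-overlapping, cheap) and only switches to exhaustive enumeration for
# the pattern/document pairs that matched at all, which keeps the common
# no-match case fast across the 1518-expression library.

.full_pattern <- function(expression, case_sensitive) {
  if (case_sensitive) expression else paste0("(?i)", expression)
}

# Enumerate all match starts of `pat` in `text`, overlapping included.
# The probe "^.{k,}?(?:pat)" finds the leftmost match starting at or after
# 0-based offset k with all lookbehind context intact; advancing k to one
# past each found start enumerates every anchored match start.
.enumerate_matches <- function(pat, text) {
  out <- list()
  k <- 0L
  n <- nchar(text)
  probe_tail <- sprintf(",}?((?:%s))", pat)
  repeat {
    if (k >= n) break
    probe <- paste0("(?s)^.{", k, probe_tail)
    m <- regexpr(probe, text, perl = TRUE)
    if (m[1] == -1L) break
    cs <- attr(m, "capture.start")[1L, ]
    cl <- attr(m, "capture.length")[1L, ]
    nm <- attr(m, "capture.names")
    w <- which(nm == "")[1L]
    start1 <- cs[[w]]
    len <- cl[[w]]
    if (len <= 0L) {
      k <- start1  # zero-length match; step past it
      next
    }
    grab <- function(g) {
      idx <- which(nm == g)
      if (length(idx) == 0L || cs[[idx[1L]]] == -1L || cl[[idx[1L]]] == 0L) {
        return(NA_character_)
      }
      substr(text, cs[[idx[1L]]], cs[[idx[1L]]] + cl[[idx[1L]]] - 1L)
    }
    out[[length(out) + 1L]] <- list(
      start0 = start1 - 1L, end0 = start1 - 1L + len,
      wt = grab("wt_res"), pos = grab("pos"), mut = grab("mut_res")
    )
    k <- start1  # next start must be strictly later
  }
  out
}

# Raw hits of one library over a character vector of texts.  Returns a list
# (per text) of data frames with 0-based spans and parsed tokens.
.match_library <- function(texts, library) {
  entries <- library$entries
  acc <- vector("list", length(texts))
  for (i in seq_along(acc)) acc[[i]] <- list()
  if (nrow(entries) == 0L || length(texts) == 0L) {
    return(lapply(acc, function(x) .empty_hits()))
  }
  for (j in seq_len(nrow(entries))) {
    pat <- .full_pattern(entries$expression[j], entries$case_sensitive[j])
    scan <- gregexpr(pat, texts, perl = TRUE)
    for (i in seq_along(texts)) {
      if (scan[[i]][1] == -1L) next
      hits <- .enumerate_matches(pat, texts[i])
      if (length(hits) == 0L) next
      df <- data.frame(
        start = vapply(hits, `[[`, integer(1), "start0"),
        end = vapply(hits, `[[`, integer(1), "end0"),
        wt_token = vapply(hits, `[[`, character(1), "wt"),
        pos_token = vapply(hits, `[[`, character(1), "pos"),
        mut_token = vapply(hits, `[[`, character(1), "mut"),
        pattern_id = entries$pattern_id[j],
        pattern_idx = j,
        stringsAsFactors = FALSE
      )
      acc[[i]][[length(acc[[i]]) + 1L]] <- df
    }
  }
  lapply(acc, function(dfs) {
    if (length(dfs) == 0L) .empty_hits() else do.call(rbind, dfs)
  })
}

.empty_hits <- function() {
  data.frame(start = integer(0), end = integer(0),
             wt_token = character(0), pos_token = character(0),
             mut_token = character(0), pattern_id = character(0),
             pattern_idx = integer(0), stringsAsFactors = FALSE)
}

# Parse raw hits into mentions, dropping candidates whose tokens do not
# normalize (unrecognized identifier, position 0 / leading zero), then
# collapse: at each span start only the longest parse survives, with
# mutation hits preferred on length ties and library order breaking the
# rest.  This reports "S56A" once as the mutation S56A rather than as a
# mutation plus an embedded residue mention of the same text.
.parse_and_collapse <- function(hits, text, allow_single_digit) {
  if (nrow(hits) == 0L) return(.empty_matches())
  wt <- vapply(hits$wt_token, .aa_one_or_na, character(1), USE.NAMES = FALSE)
  ok <- !is.na(wt) & grepl("^[1-9][0-9]*$", hits$pos_token)
  mut <- rep(NA_character_, nrow(hits))
  has_mut <- !is.na(hits$mut_token)
  mut[has_mut] <- vapply(hits$mut_token[has_mut], .aa_one_or_na,
                         character(1), USE.NAMES = FALSE)
  ok <- ok & !(has_mut & is.na(mut))
  if (!allow_single_digit) {
    ok <- ok & nchar(hits$pos_token) > 1L
  }
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) == 0L) return(.empty_matches())
  wt <- wt[ok]; mut <- mut[ok]
  key <- paste0(wt, hits$pos_token, ifelse(is.na(mut), "", mut))
  df <- data.frame(
    start = hits$start, end = hits$end,
    raw_text = substr(rep(text, nrow(hits)), hits$start + 1L, hits$end),
    pattern_id = hits$pattern_id, key = key,
    wild_type = wt, position = hits$pos_token, mutant = mut,
    stringsAsFactors = FALSE
  )
  ord <- order(df$start, -df$end, is.na(df$mutant), hits$pattern_idx)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.empty_matches <- function() {
  data.frame(start = integer(0), end = integer(0), raw_text = character(0),
             pattern_id = character(0), key = character(0),
             wild_type = character(0), position = character(0),
             mutant = character(0), stringsAsFactors = FALSE)
}

.default_single_digit <- function(library) {
  # The mutation-only library historically required two-digit positions;
  # the residue libraries accept single digits so that mentions near the
  # start of a sequence are not thrown away.
  !(library$name %in% c("mf", "mf_cut"))
}

#' Extract residue and mutation mentions from a document
#'
#' Applies every expression of a pattern library to the document text,
#' parses the named capture groups of each hit into a normalized mention,
#' and collapses hits that describe the same textual event (same span
#' start; the longest parse wins, so a wNm mutation is not additionally
#' reported as its embedded residue).  Matches are returned in ascending
#' span order with 0-based half-open character offsets.
#'
#' @param doc An `rf_document` or a single character string.
#' @param library A `regex_library` (see [get_library()]).
#' @param allow_single_digit Accept single-digit positions ("G2")?  Default
#'   `NULL` means the library's convention: `TRUE` for the residue
#'   libraries, `FALSE` for the mutation-only `mf` libraries.
#' @param strip_bib Remove a trailing bibliography first (see
#'   [strip_bibliography()]).
#' @param abstract_only Restrict matching to the document's `abstract`
#'   region when the section map declares one.
#' @return An object of class `extraction_result`: `doc_id`, `matches` (a
#'   data frame with columns `start`, `end`, `raw_text`, `pattern_id`,
#'   `key`, `wild_type`, `position`, `mutant`) and `unique_mentions` (keys
#'   in first-occurrence order).
#' @examples
#' extract_mentions("the A64G mutant of Ser 56", get_library("rf2"))
#' @export
extract_mentions <- function(doc, library, allow_single_digit = NULL,
                             strip_bib = FALSE, abstract_only = FALSE) {
  res <- extract_corpus(list(.as_document(doc)), library,
                        allow_single_digit = allow_single_digit,
                        strip_bib = strip_bib, abstract_only = abstract_only)
  res[[1L]]
}

#' Extract mentions from a corpus of documents
#'
#' Vectorized form of [extract_mentions()]; the library is scanned once
#' per expression across all documents.
#'
#' @inheritParams extract_mentions
#' @param documents A named list of `rf_document` objects (or character
#'   texts; see [read_documents()]).
#' @return Named list of `extraction_result` objects, one per document.
#' @export
extract_corpus <- function(documents, library, allow_single_digit = NULL,
                           strip_bib = FALSE, abstract_only = FALSE) {
  stopifnot(inherits(library, "regex_library"))
  docs <- .as_document_list(documents)
  if (is.null(allow_single_digit)) {
    allow_single_digit <- .default_single_digit(library)
  }
  if (strip_bib) {
    docs <- lapply(docs, strip_bibliography)
  }
  texts <- vapply(docs, function(d) {
    if (abstract_only && !is.null(d$section_map)) {
      row <- d$section_map[d$section_map$section == "abstract", , drop = FALSE]
      if (nrow(row) > 0L) {
        return(substr(d$text, row$start[1] + 1L, row$end[1]))
      }
    }
    d$text
  }, character(1))
  raw <- .match_library(texts, library)
  out <- lapply(seq_along(docs), function(i) {
    matches <- .parse_and_collapse(raw[[i]], texts[i], allow_single_digit)
    structure(
      list(doc_id = docs[[i]]$doc_id, matches = matches,
           unique_mentions = unique(matches$key)),
      class = "extraction_result"
    )
  })
  names(out) <- vapply(docs, `[[`, character(1), "doc_id")
  out
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("<extraction_result> %s: %d matches, %d unique mentions\n",
              x$doc_id, nrow(x$matches), length(x$unique_mentions)))
  if (length(x$unique_mentions)) {
    cat(" ", paste(x$unique_mentions, collapse = " "), "\n")
  }
  invisible(x)
}

#' Count mentions of an extraction result
#'
#' `single` mode reports each unique mention key once per document (the
#' default reporting style: a mention anywhere in an article is a reason to
#' read it); `full` mode reports every textual occurrence.
#'
#' @param result An `extraction_result`.
#' @param mode `"single"` or `"full"`.
#' @return Named integer vector mapping mention keys (in first-occurrence
#'   order) to counts.
#' @examples
#' r <- extract_mentions("S56 and S56 near A64G", get_library("rf1"))
#' count_mentions(r, "single")
#' count_mentions(r, "full")
#' @export
count_mentions <- function(result, mode = c("single", "full")) {
  stopifnot(inherits(result, "extraction_result"))
  mode <- match.arg(mode)
  keys <- result$matches$key
  if (length(keys) == 0L) {
    return(structure(integer(0), names = character(0)))
  }
  order_keys <- unique(keys)
  counts <- if (mode == "single") {
    structure(rep(1L, length(order_keys)), names = order_keys)
  } else {
    tab <- table(keys)
    structure(as.integer(tab[order_keys]), names = order_keys)
  }
  counts
}
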