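# Scoring against a gold standard: TP/FP/FN bookkeeping, precision, recall
# and F-beta.  True negatives are never computed -- "a residue not
# mentioned and not returned" is not a useful event for this task.

#' Construct a gold standard
#'
#' @param docs Named list: one element per document, each a named numeric
#'   vector mapping mention keys to expected counts (use count 1 throughout
#'   for single-count gold).  Keys must be valid mention renderings such as
#'   `"S56"` or `"A64G"`.
#' @return An object of class `gold_standard`.
#' @export
gold_standard <- function(docs) {
  stopifnot(is.list(docs))
  if (length(docs) > 0L && (is.null(names(docs)) || any(!nzchar(names(docs))))) {
    stop("`docs` must be a named list (document ids)", call. = FALSE)
  }
  for (id in names(docs)) {
    keys <- names(docs[[id]])
    if (length(docs[[id]]) > 0L && is.null(keys)) {
      stop(sprintf("gold entries for document \"%s\" must be named by key", id),
           call. = FALSE)
    }
    for (k in keys) {
      tryCatch(parse_mention_key(k), error = function(e) {
        stop(sprintf("document \"%s\": invalid gold key \"%s\"", id, k),
             call. = FALSE)
      })
    }
  }
  structure(list(docs = lapply(docs, function(x) {
    storage.mode(x) <- "integer"
    x
  })), class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  total <- sum(vapply(x$docs, function(d) sum(d), numeric(1)), 0)
  cat(sprintf("<gold_standard> %d documents, %d mention occurrences\n",
              length(x$docs), total))
  invisible(x)
}

#' Read a gold-standard annotation file
#'
#' One line per document: `doc_id<TAB>key[:count][,key[:count]...]`.
#' Counts default to 1; `#` lines are comments.  A document with no
#' expected mentions is a bare `doc_id` line.
#'
#' @param path File path.
#' @return A `gold_standard`.
#' @export
read_gold <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  docs <- list()
  for (line in lines) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    doc_id <- fields[1]
    counts <- integer(0)
    if (length(fields) > 1L && nzchar(fields[2])) {
      items <- strsplit(fields[2], ",", fixed = TRUE)[[1]]
      keys <- sub(":.*$", "", items)
      n <- ifelse(grepl(":", items, fixed = TRUE),
                  suppressWarnings(as.integer(sub("^.*:", "", items))), 1L)
      if (anyNA(n)) {
        stop(sprintf("document \"%s\": malformed count in gold file", doc_id),
             call. = FALSE)
      }
      counts <- structure(n, names = keys)
    }
    docs[[doc_id]] <- counts
  }
  gold_standard(docs)
}

#' Write a gold standard to file
#'
#' @param gold A `gold_standard`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  stopifnot(inherits(gold, "gold_standard"))
  lines <- vapply(names(gold$docs), function(id) {
    cc <- gold$docs[[id]]
    if (length(cc) == 0L) return(id)
    paste0(id, "\t", paste0(names(cc), ":", cc, collapse = ","))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Precision and recall from error counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`.  Degenerate
#' denominators follow the usual conventions: with nothing retrieved,
#' precision is 1 when nothing was expected and 0 otherwise; with nothing
#' expected, recall is 1.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `c(precision = , recall = )`.
#' @examples
#' precision_recall(66, 3, 102)
#' @export
precision_recall <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0) || anyNA(c(tp, fp, fn))) {
    stop("tp, fp and fn must be non-negative", call. = FALSE)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 1
  c(precision = precision, recall = recall)
}

#' F-beta measure
#'
#' `F_beta = ((beta^2 + 1) * P * R) / (beta^2 * P + R)`, returning 0 when
#' the denominator vanishes.  `beta = 1` balances precision and recall;
#' larger `beta` weights recall more heavily (at `beta = 0` the measure
#' reduces to precision, and it tends to recall as `beta` grows).  Recall
#' is often the quantity to protect in literature mining -- false positives
#' can be filtered by later inspection, false negatives are simply lost --
#' which argues for `beta > 1`.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @param beta Non-negative weight (vectorized).
#' @return Numeric vector of F scores, one per `beta`.
#' @examples
#' f_beta(0.957, 0.393, beta = c(1, 2))
#' @export
f_beta <- function(precision, recall, beta = 1) {
  if (any(beta < 0) || anyNA(beta)) {
    stop("`beta` must be non-negative", call. = FALSE)
  }
  if (precision < 0 || precision > 1 || recall < 0 || recall > 1) {
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  }
  num <- (beta^2 + 1) * precision * recall
  den <- beta^2 * precision + recall
  ifelse(den == 0, 0, num / den)
}

.as_counts_list <- function(extracted, mode) {
  if (inherits(extracted, "extraction_result")) {
    extracted <- stats::setNames(list(extracted), extracted$doc_id)
  }
  stopifnot(is.list(extracted))
  lapply(extracted, function(x) {
    if (inherits(x, "extraction_result")) count_mentions(x, mode) else x
  })
}

new_eval_result <- function(tp, fp, fn, beta = c(1, 2)) {
  pr <- precision_recall(tp, fp, fn)
  fs <- vapply(beta, function(b) f_beta(pr[["precision"]], pr[["recall"]], b),
               numeric(1))
  names(fs) <- as.character(beta)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = pr[["precision"]], recall = pr[["recall"]],
                 beta = beta, f_scores = fs),
            class = "eval_result")
}

#' Score extracted mentions against a gold standard
#'
#' In `single` mode each document contributes set-wise counts: TP is the
#' number of gold keys retrieved, FP the keys retrieved but not expected,
#' FN the gold keys missed.  In `full` mode counts are multiset-wise per
#' key: TP gains `min(extracted, gold)`, FP the extracted excess, FN the
#' gold excess.  Documents present on only one side are treated as empty on
#' the other.
#'
#' @param extracted Named list (by document id) of key->count vectors, of
#'   `extraction_result` objects, or a single `extraction_result`.
#' @param gold A `gold_standard`.
#' @param mode `"single"` or `"full"`.
#' @param beta F-measure weights to report.
#' @return An `eval_result` with fields `tp`, `fp`, `fn`, `precision`,
#'   `recall` and `f_scores` (named by beta).
#' @examples
#' g <- gold_standard(list(d1 = c(A64G = 1, S56 = 1)))
#' score_extraction(list(d1 = c(A64G = 1)), g, mode = "single")
#' @export
score_extraction <- function(extracted, gold, mode = c("single", "full"),
                             beta = c(1, 2)) {
  stopifnot(inherits(gold, "gold_standard"))
  mode <- match.arg(mode)
  counts <- .as_counts_list(extracted, mode)
  ids <- union(names(counts), names(gold$docs))
  tp <- fp <- fn <- 0L
  for (id in ids) {
    e <- counts[[id]]
    g <- gold$docs[[id]]
    if (is.null(e)) e <- integer(0)
    if (is.null(g)) g <- integer(0)
    if (mode == "single") {
      ek <- names(e)
      gk <- names(g)
      tp <- tp + length(intersect(ek, gk))
      fp <- fp + length(setdiff(ek, gk))
      fn <- fn + length(setdiff(gk, ek))
    } else {
      keys <- union(names(e), names(g))
      for (k in keys) {
        ne <- if (k %in% names(e)) e[[k]] else 0L
        ng <- if (k %in% names(g)) g[[k]] else 0L
        tp <- tp + min(ne, ng)
        fp <- fp + max(ne - ng, 0L)
        fn <- fn + max(ng - ne, 0L)
      }
    }
  }
  new_eval_result(tp, fp, fn, beta = beta)
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.3f  recall %.3f  %s\n",
              round(x$precision, 3), round(x$recall, 3),
              paste(sprintf("F%s %.3f", names(x$f_scores),
                            round(x$f_scores, 3)), collapse = "  ")))
  invisible(x)
}

#' Format an evaluation result as a report row
#'
#' Tab-separated `TP FP FN P R F...` with ratios rounded to three decimals
#' (round-half-even), mirroring the layout of published performance tables.
#'
#' @param result An `eval_result`.
#' @param label Optional leading label column.
#' @return A single string (no trailing newline).
#' @export
format_eval_report <- function(result, label = NULL) {
  stopifnot(inherits(result, "eval_result"))
  fmt3 <- function(v) sprintf("%.3f", round(v, 3))
  fields <- c(label, result$tp, result$fp, result$fn,
              fmt3(result$precision), fmt3(result$recall),
              fmt3(result$f_scores))
  paste(fields, collapse = "\t")
}

.FP_CLASSES <- c("motif_name", "equipment_substrate", "bibliography_reference",
                 "protein_ground_name", "short_name", "pdf_artifact",
                 "formula_nomenclature")
.FN_CLASSES <- c("in_image", "regex_not_found")

#' Summarize analyst-labelled error causes
#'
#' Tallies error-cause labels (for false positives: motif names, equipment
#' or substrate names, bibliography entries, protein/ground names, short
#' names, PDF-conversion artifacts, chemical formulas; for false negatives:
#' mention embedded in an image, or no matching expression in the library).
#' A record may carry several labels and then contributes to each class, so
#' incidences can sum to more than the number of records; percentages are
#' of total labelled incidences.
#'
#' @param labels Either a named numeric vector of per-class counts, or a
#'   list with one character vector of labels per record.
#' @param type `"fp"` or `"fn"`, selecting the class vocabulary.
#' @return Data frame with columns `class`, `count`, `percent` for every
#'   class with a positive count, in vocabulary order.
#' @examples
#' error_breakdown(c(in_image = 15, regex_not_found = 7), type = "fn")
#' @export
error_breakdown <- function(labels, type = c("fp", "fn")) {
  type <- match.arg(type)
  vocab <- if (type == "fp") .FP_CLASSES else .FN_CLASSES
  if (is.list(labels)) {
    flat <- unlist(labels, use.names = FALSE)
    counts <- table(factor(flat, levels = vocab))
    unknown <- setdiff(unique(flat), vocab)
  } else if (is.numeric(labels)) {
    unknown <- setdiff(names(labels), vocab)
    counts <- structure(rep(0, length(vocab)), names = vocab)
    counts[names(labels)[names(labels) %in% vocab]] <-
      labels[names(labels) %in% vocab]
  } else if (is.null(labels) || length(labels) == 0L) {
    counts <- structure(rep(0, length(vocab)), names = vocab)
    unknown <- character(0)
  } else {
    stop("`labels` must be a named count vector or a list of label vectors",
         call. = FALSE)
  }
  if (length(unknown) > 0L) {
    stop(sprintf("unknown error class(es): %s (valid: %s)",
                 paste(unknown, collapse = ", "),
                 paste(vocab, collapse = ", ")), call. = FALSE)
  }
  counts <- as.numeric(counts[vocab])
  keep <- counts > 0
  total <- sum(counts)
  data.frame(
    class = vocab[keep],
    count = counts[keep],
    percent = if (total > 0) 100 * counts[keep] / total else numeric(0),
    stringsAsFactors = FALSE
  )
}
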