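# Document container and text I/O.
#
# Coordinates throughout the package are 0-based, half-open character
# offsets over the NFC-normalized text, so `substr(text, start + 1, end)`
# recovers any recorded span.

#' Create a document
#'
#' @param doc_id Opaque document identifier.
#' @param text Document text (normalized to Unicode NFC).
#' @param section_map Optional data frame with columns `section`, `start`,
#'   `end` labelling non-overlapping regions (e.g. `abstract`, `body`,
#'   `bibliography`) as 0-based half-open character ranges.
#' @return An object of class `rf_document`.
#' @export
document <- function(doc_id, text, section_map = NULL) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  text <- stringi::stri_trans_nfc(text)
  if (!is.null(section_map)) {
    stopifnot(is.data.frame(section_map),
              all(c("section", "start", "end") %in% names(section_map)))
    n <- nchar(text)
    bad <- section_map$start < 0 | section_map$end > n |
      section_map$start > section_map$end
    if (any(bad)) {
      stop("section_map ranges must lie within [0, nchar(text)]", call. = FALSE)
    }
  }
  structure(list(doc_id = doc_id, text = text, section_map = section_map),
            class = "rf_document")
}

#' @export
print.rf_document <- function(x, ...) {
  cat(sprintf("<rf_document> %s: %d chars", x$doc_id, nchar(x$text)))
  if (!is.null(x$section_map)) {
    cat(sprintf(" [%s]", paste(x$section_map$section, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

.as_document <- function(x, doc_id = "doc") {
  if (inherits(x, "rf_document")) return(x)
  document(doc_id, x)
}

#' Read documents from disk
#'
#' Two layouts are accepted.  A directory is read as one UTF-8 text file
#' per document (`doc_id` = file name without extension).  A single file is
#' read as a corpus file of tab-separated `doc_id<TAB>text` records, one
#' per line, with `\\t`, `\\n` and `\\\\` escapes in the text field (the
#' format written by [write_corpus_file()]).
#'
#' @param path Directory of `.txt` files or a corpus file.
#' @return Named list of `rf_document` objects.
#' @export
read_documents <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    docs <- lapply(files, function(f) {
      text <- paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                    collapse = "\n")
      document(sub("\\.txt$", "", basename(f)), text)
    })
    names(docs) <- vapply(docs, `[[`, character(1), "doc_id")
    return(docs)
  }
  if (!file.exists(path)) {
    stop(sprintf("no such file or directory: %s", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  docs <- lapply(lines, function(line) {
    tab <- regexpr("\t", line, fixed = TRUE)
    if (tab == -1L) {
      stop("corpus file records must be \"doc_id<TAB>text\"", call. = FALSE)
    }
    doc_id <- substr(line, 1L, tab - 1L)
    text <- .unescape_corpus_text(substr(line, tab + 1L, nchar(line)))
    document(doc_id, text)
  })
  names(docs) <- vapply(docs, `[[`, character(1), "doc_id")
  docs
}

.escape_corpus_text <- function(text) {
  text <- gsub("\\", "\\\\", text, fixed = TRUE)
  text <- gsub("\t", "\\t", text, fixed = TRUE)
  gsub("\n", "\\n", text, fixed = TRUE)
}

.unescape_corpus_text <- function(text) {
  if (!grepl("\\", text, fixed = TRUE)) return(text)
  # split on literal "\\" first so its halves are unescaped independently;
  # the sentinel keeps strsplit from dropping a trailing empty piece
  parts <- strsplit(paste0(text, "\u0001"), "\\\\", fixed = TRUE)[[1]]
  parts <- gsub("\\t", "\t", parts, fixed = TRUE)
  parts <- gsub("\\n", "\n", parts, fixed = TRUE)
  sub("\u0001$", "", paste(parts, collapse = "\\"))
}

#' Write documents as a single corpus file
#'
#' @param documents Named list of `rf_document` objects (or character texts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_file <- function(documents, path) {
  docs <- .as_document_list(documents)
  lines <- vapply(docs, function(d) {
    paste0(d$doc_id, "\t", .escape_corpus_text(d$text))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.as_document_list <- function(documents) {
  if (inherits(documents, "rf_document")) {
    documents <- list(documents)
  }
  ids <- names(documents)
  docs <- lapply(seq_along(documents), function(i) {
    d <- documents[[i]]
    if (inherits(d, "rf_document")) return(d)
    id <- if (!is.null(ids) && nzchar(ids[i])) ids[i] else sprintf("doc%d", i)
    document(id, d)
  })
  names(docs) <- vapply(docs, `[[`, character(1), "doc_id")
  docs
}

.BIB_HEADING_RE <- "(?mi)^[ \t]*(references|bibliography|literature cited)[ \t]*$"

#' Remove the bibliography section of a document
#'
#' Scans for a bibliography heading ("References", "Bibliography" or
#' "Literature Cited", case-insensitive, alone on its line).  If such a
#' heading starts in the final 50% of the text, everything from the heading
#' onward is removed and the removed range (in the original coordinates) is
#' recorded in the document's `section_map`; otherwise the document is
#' returned unchanged.  Reference lists yield almost no true residue
#' mentions, so stripping them trims false positives and scanning time at
#' essentially no recall cost.
#'
#' @param doc An `rf_document` or a single character string.
#' @return Same type as the input, with the bibliography removed.
#' @export
strip_bibliography <- function(doc) {
  was_char <- !inherits(doc, "rf_document")
  d <- .as_document(doc)
  n <- nchar(d$text)
  m <- gregexpr(.BIB_HEADING_RE, d$text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    starts0 <- as.integer(m) - 1L
    hit <- starts0[starts0 >= n / 2]
    if (length(hit) > 0L) {
      cutoff0 <- hit[1]
      removed <- data.frame(section = "bibliography",
                            start = cutoff0, end = n,
                            stringsAsFactors = FALSE)
      d$section_map <- rbind(d$section_map, removed)
      d$text <- substr(d$text, 1L, cutoff0)
    }
  }
  if (was_char) d$text else d
}
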