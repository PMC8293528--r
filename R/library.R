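# Pattern library container, the eight shipped variants and the pattern-file
# reader/writer.

.KNOWN_LIBRARIES <- c("mf", "mf_cut", "rf1", "rf1_cut",
                      "rf2", "rf2_cut", "rf3", "rf3_cut")

.lib_cache <- new.env(parent = emptyenv())

new_regex_library <- function(name, entries) {
  required <- c("pattern_id", "expression", "case_sensitive", "provenance", "cut")
  stopifnot(is.data.frame(entries), all(required %in% names(entries)))
  rownames(entries) <- NULL
  structure(list(name = name, entries = entries), class = "regex_library")
}

#' @export
length.regex_library <- function(x) nrow(x$entries)

#' @export
print.regex_library <- function(x, ...) {
  cat(sprintf("<regex_library> %s: %d expressions (%d flagged cut)\n",
              x$name, nrow(x$entries), sum(x$entries$cut)))
  invisible(x)
}

#' Names of the shipped pattern libraries
#'
#' @return Character vector of the eight library names: the mutation-only
#'   library `mf`, the residue libraries `rf1` (no-space forms), `rf2`
#'   (adds spaced forms) and `rf3` (adds bare capital+number forms and the
#'   broad phrase patterns), each with a reduced `*_cut` variant.
#' @export
library_names <- function() .KNOWN_LIBRARIES

#' Retrieve a shipped pattern library
#'
#' Libraries are generated from their defining nomenclature rules on first
#' use and cached for the session.  `rf1`, `rf2` and `rf3` are nested by
#' construction (`rf2` = `rf1` + spaced forms, `rf3` = `rf2` + bare and
#' phrase forms), so their match sets are nested on any text.  The `rf3`
#' library has 1518 expressions; `rf3_cut` keeps the six most common
#' nomenclatures ({one-letter, three-letter, full-name} crossed with
#' {no space, one space}).
#'
#' @param name One of [library_names()].
#' @return A `regex_library`.
#' @examples
#' length(get_library("rf3"))
#' length(get_library("rf3_cut"))
#' @export
get_library <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% .KNOWN_LIBRARIES)) {
    stop(sprintf("unknown library \"%s\"; valid names: %s",
                 as.character(name)[1],
                 paste(.KNOWN_LIBRARIES, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(.lib_cache[[name]])) {
    return(.lib_cache[[name]])
  }
  if (is.null(.lib_cache[["..rf_entries"]])) {
    .lib_cache[["..rf_entries"]] <- .build_all_rf_entries()
    .lib_cache[["..mf_entries"]] <- .build_mf_entries()
  }
  rf <- .lib_cache[["..rf_entries"]]
  mf <- .lib_cache[["..mf_entries"]]
  base <- sub("_cut$", "", name)
  entries <- switch(base,
    mf  = mf,
    rf1 = rf[rf$provenance == "rf1", , drop = FALSE],
    rf2 = rf[rf$provenance %in% c("rf1", "rf2"), , drop = FALSE],
    rf3 = rf
  )
  lib <- new_regex_library(base, entries)
  if (grepl("_cut$", name)) {
    lib <- cut_library(lib)
    lib$name <- name
  }
  .lib_cache[[name]] <- lib
  lib
}

#' Reduce a library to its most common nomenclature patterns
#'
#' Keeps only the entries flagged as cut members, i.e. the expressions
#' reflecting the most common residue/mutation nomenclature.  Because
#' scanning time is proportional to the number of expressions, the cut
#' library trades a modest loss of recall for a several hundredfold
#' reduction in work (1518 vs 6 expressions for the `rf3` family).
#' Idempotent: cutting a cut library returns it unchanged.
#'
#' @param library A `regex_library`.
#' @return A `regex_library` whose entries are the cut-flagged subset.
#' @examples
#' length(cut_library(get_library("rf3")))
#' @export
cut_library <- function(library) {
  stopifnot(inherits(library, "regex_library"))
  entries <- library$entries[library$entries$cut, , drop = FALSE]
  name <- if (grepl("_cut$", library$name)) library$name
          else paste0(library$name, "_cut")
  new_regex_library(name, entries)
}

#' @rdname cut_library
#' @param x A `regex_library` (alias so that `cut()` works on libraries).
#' @param ... Ignored.
#' @export
cut.regex_library <- function(x, ...) cut_library(x)

.has_named_group <- function(expression, group) {
  grepl(sprintf("(?P<%s>", group), expression, fixed = TRUE) ||
    grepl(sprintf("(?<%s>", group), expression, fixed = TRUE)
}

.check_entry_compiles <- function(expression, case_sensitive) {
  pat <- if (case_sensitive) expression else paste0("(?i)", expression)
  tryCatch({
    suppressWarnings(regexpr(pat, "", perl = TRUE))
    TRUE
  }, error = function(e) conditionMessage(e))
}

#' Load a pattern file
#'
#' Reads a pattern library from a flat text file: one extended (PCRE)
#' regular expression per line, `#` lines are comments, blank lines are
#' skipped.  A trailing tab-separated `[CASE_SENSITIVE]` marker makes that
#' line case-sensitive (lines without it are matched case-insensitively,
#' the convention of the MutationFinder file format); a trailing `[CUT]`
#' marker flags the entry as a member of the cut subset.  Every expression
#' must contain the named capture groups `wt_res` and `pos`; `mut_res` is
#' optional and distinguishes mutation-only patterns.
#'
#' @param path Path to the pattern file.
#' @param name Name recorded on the returned library.
#' @return A `regex_library` with one entry per pattern line, in file order.
#' @seealso [write_pattern_file()]
#' @export
load_pattern_file <- function(path, name = "custom") {
  if (!file.exists(path)) {
    stop(sprintf("pattern file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    line <- sub("\r$", "", lines[[i]])
    if (!nzchar(trimws(line)) || grepl("^\\s*#", line)) next
    case_sensitive <- FALSE
    cut_flag <- FALSE
    repeat {
      trimmed <- sub("[\t ]+\\[(CASE_SENSITIVE|CUT)\\]\\s*$", "", line)
      if (identical(trimmed, line)) break
      marker <- regmatches(line, regexpr("\\[(CASE_SENSITIVE|CUT)\\]\\s*$", line))
      if (grepl("CASE_SENSITIVE", marker)) case_sensitive <- TRUE else cut_flag <- TRUE
      line <- trimmed
    }
    expression <- line
    ok <- .check_entry_compiles(expression, case_sensitive)
    if (!isTRUE(ok)) {
      stop(sprintf("line %d of %s does not compile: %s", i, path, ok),
           call. = FALSE)
    }
    for (group in c("wt_res", "pos")) {
      if (!.has_named_group(expression, group)) {
        stop(sprintf("line %d of %s is missing required named group \"%s\"",
                     i, path, group), call. = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <- .new_entries(
      pattern_id = sprintf("L%04d", i), expression = expression,
      provenance = name, cut = cut_flag, case_sensitive = case_sensitive
    )
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    .new_entries(character(), character(), character(), logical(), logical())
  new_regex_library(name, entries)
}

#' Write a library to a pattern file
#'
#' Emits the flat one-pattern-per-line format read by
#' [load_pattern_file()], with `[CASE_SENSITIVE]` / `[CUT]` markers as
#' needed and a comment header naming the library.
#'
#' @param library A `regex_library`.
#' @param path Output file path (UTF-8, LF line endings).
#' @return `path`, invisibly.
#' @export
write_pattern_file <- function(library, path) {
  stopifnot(inherits(library, "regex_library"))
  e <- library$entries
  lines <- e$expression
  lines <- paste0(lines, ifelse(e$case_sensitive, "\t[CASE_SENSITIVE]", ""))
  lines <- paste0(lines, ifelse(e$cut, "\t[CUT]", ""))
  header <- sprintf("# %s pattern library (%d expressions)",
                    library$name, nrow(e))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(header, lines)), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
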