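# Deterministic synthetic corpus generator.
#
# Emulates full-text articles at desk scale: each document is filler prose
# with planted residue/mutation mentions across the nomenclature variants,
# plus distractor fragments drawn from the error classes observed for the
# broad library (motif names, equipment, bibliography entries, protein
# names, short names, PDF artifacts, chemical formulas), optionally with a
# citation-style bibliography tail that never contains planted mentions.
# The exact planted spans form the gold standard, so precision/recall of
# any library is measurable without external corpora.

.FORM_NAMES <- c("one_nospace", "one_space", "three_nospace", "three_space",
                 "full_name", "wnm", "arrow", "single_digit")

.MUTATION_FORMS <- c("wnm", "arrow")

#' Configuration for the synthetic corpus generator
#'
#' Form-mix and distractor-mix weights are sampling probabilities (any
#' non-negative weights; they are normalized).  The default mix leans on
#' the no-space one-letter/three-letter forms, which dominate real text,
#' but keeps every variant present.  Mention positions are drawn from
#' 10-400 (1-9 for the single-digit form); numerals appearing in
#' bibliography distractors are drawn from 600-999 so that bibliography
#' false positives can never collide with a planted mention key.
#'
#' @param n_docs Number of documents.
#' @param seed Integer seed; identical config + seed reproduces the corpus
#'   byte for byte.
#' @param mentions_per_doc Length-2 integer range (inclusive).
#' @param form_mix Named non-negative weights over
#'   `c("one_nospace", "one_space", "three_nospace", "three_space",
#'   "full_name", "wnm", "arrow", "single_digit")`.
#' @param distractor_mix Named non-negative weights over the seven
#'   false-positive classes (see [error_breakdown()]).
#' @param distractors_per_doc Length-2 integer range (inclusive).
#' @param include_bibliography Append a "References" tail to each document.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(n_docs = 20L,
                          seed = 1L,
                          mentions_per_doc = c(3L, 8L),
                          form_mix = c(one_nospace = 0.25, one_space = 0.10,
                                       three_nospace = 0.15, three_space = 0.10,
                                       full_name = 0.10, wnm = 0.15,
                                       arrow = 0.05, single_digit = 0.10),
                          distractor_mix = c(motif_name = 1,
                                             equipment_substrate = 1,
                                             bibliography_reference = 1,
                                             protein_ground_name = 1,
                                             short_name = 1,
                                             pdf_artifact = 1,
                                             formula_nomenclature = 1),
                          distractors_per_doc = c(2L, 5L),
                          include_bibliography = TRUE) {
  stopifnot(n_docs >= 1, length(mentions_per_doc) == 2L,
            mentions_per_doc[1] >= 0, mentions_per_doc[1] <= mentions_per_doc[2],
            length(distractors_per_doc) == 2L,
            distractors_per_doc[1] >= 0,
            distractors_per_doc[1] <= distractors_per_doc[2])
  unknown_forms <- setdiff(names(form_mix), .FORM_NAMES)
  if (length(unknown_forms)) {
    stop("unknown form(s) in form_mix: ", paste(unknown_forms, collapse = ", "),
         call. = FALSE)
  }
  form_mix <- form_mix[.FORM_NAMES[.FORM_NAMES %in% names(form_mix)]]
  if (any(form_mix < 0) || any(distractor_mix < 0)) {
    stop("mix weights must be non-negative", call. = FALSE)
  }
  if (mentions_per_doc[2] > 0 && sum(form_mix) <= 0) {
    stop("form_mix needs at least one positive weight when mentions are requested",
         call. = FALSE)
  }
  bad_classes <- setdiff(names(distractor_mix), .FP_CLASSES)
  if (length(bad_classes)) {
    stop("unknown distractor class(es): ", paste(bad_classes, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 mentions_per_doc = as.integer(mentions_per_doc),
                 form_mix = form_mix, distractor_mix = distractor_mix,
                 distractors_per_doc = as.integer(distractors_per_doc),
                 include_bibliography = isTRUE(include_bibliography)),
            class = "corpus_config")
}

#' Render a mention in a given nomenclature form
#'
#' The returned fragment re-extracts to exactly the given mention under the
#' broad (`rf3`) library.
#'
#' @param mention A `residue_mention`.
#' @param form One of the form-mix names (see [corpus_config()]).
#' @return A text fragment such as `"Ser 56"` or `"A64G"`.
#' @examples
#' plant_form(normalize_mention("S", 56), "three_space")
#' plant_form(normalize_mention("A", 64, "G"), "wnm")
#' @export
plant_form <- function(mention, form) {
  stopifnot(inherits(mention, "residue_mention"))
  if (!form %in% .FORM_NAMES) {
    stop("unknown form: ", form, call. = FALSE)
  }
  has_mut <- !is.na(mention$mutant)
  if (form %in% .MUTATION_FORMS && !has_mut) {
    stop(sprintf("form \"%s\" requires a mutation mention", form), call. = FALSE)
  }
  if (!(form %in% .MUTATION_FORMS) && has_mut) {
    stop(sprintf("form \"%s\" requires a plain residue mention", form),
         call. = FALSE)
  }
  idx <- match(mention$wild_type, .AA$one_letter)
  three <- .AA$three_letter[idx]
  full <- .AA$full_name[idx]
  pos <- mention$position
  switch(form,
    one_nospace = paste0(mention$wild_type, pos),
    one_space = paste(mention$wild_type, pos),
    three_nospace = paste0(three, pos),
    three_space = paste(three, pos),
    full_name = paste(full, pos),
    wnm = paste0(mention$wild_type, pos, mention$mutant),
    arrow = paste0(mention$wild_type, pos, "→", mention$mutant),
    single_digit = {
      if (nchar(pos) != 1L) {
        stop("single_digit form requires a position of 1-9", call. = FALSE)
      }
      paste0(mention$wild_type, pos)
    }
  )
}

#' Forms guaranteed to be recovered by a library
#'
#' Maps a shipped library to the subset of generator forms its expressions
#' cover, used to build corpora on which that library's recall is exactly 1.
#'
#' @param name A library name (see [library_names()]).
#' @return Character vector of form names.
#' @export
covered_forms <- function(name) {
  base <- c("one_nospace", "three_nospace", "wnm", "single_digit")
  spaced <- c("one_space", "three_space", "full_name")
  switch(name,
    mf = , mf_cut = "wnm",
    rf1 = , rf1_cut = base,
    rf2 = , rf2_cut = , rf3_cut = c(base, spaced),
    rf3 = c(base, spaced, "arrow"),
    stop("unknown library: ", name, call. = FALSE)
  )
}

# Filler vocabulary: lowercase, digit-free, free of amino-acid names and of
# capital-letter+digit collisions, so filler text can never produce a match.
.FILLER_WORDS <- c(
  "the", "channel", "gating", "current", "membrane", "voltage", "protein",
  "binding", "was", "measured", "under", "control", "conditions", "and",
  "with", "activation", "kinetics", "were", "slower", "after", "treatment",
  "of", "purified", "samples", "in", "buffer", "solution", "expression",
  "construct", "showed", "robust", "function", "during", "recordings",
  "from", "transfected", "cells", "suggesting", "a", "conserved", "role",
  "for", "this", "region", "structural", "data", "support", "model",
  "folding", "stability", "upon", "ligand", "interaction"
)

.filler_sentence <- function(n_words) {
  words <- sample(.FILLER_WORDS, n_words, replace = TRUE)
  paste0(paste(words, collapse = " "), ".")
}

# Distractor templates per false-positive class.  Each class has at least
# one member the broad library will match (the "{N}" slot is filled with a
# number from 600-999 for classes that must not collide with gold keys).
.distractor_text <- function(class) {
  pick <- function(x) x[[sample.int(length(x), 1L)]]
  n_big <- function() sample(600:999, 1L)
  switch(class,
    motif_name = pick(list(
      sprintf("the S%d segment", sample(1:6, 1L)),
      sprintf("the S%d-S%d linker", sample(1:5, 1L), sample(2:6, 1L)),
      "the P1 helix"
    )),
    equipment_substrate = pick(list(
      "a C18 reverse-phase column",
      sprintf("a T%d culture flask", sample(c(25L, 75L), 1L)),
      sprintf("an S%d gel filtration column", n_big())
    )),
    bibliography_reference = pick(list(
      sprintf("Proc Natl Acad Sci U S A %d: 141-146, 1999", n_big()),
      sprintf("J Physiol %d, no. 2 (1999)", n_big())
    )),
    protein_ground_name = pick(list(
      "the H3 histone tail",
      sprintf("p%d S6 kinase", sample(c(70L, 90L), 1L)),
      "T7 polymerase"
    )),
    short_name = pick(list("the D2 receptor", "the M2 helix")),
    pdf_artifact = pick(list(
      sprintf("Ser* %d", n_big()),
      sprintf("T~%d", n_big())
    )),
    formula_nomenclature = pick(list(
      "C6H12O6", sprintf("H2O2 at %d mM", sample(1:9, 1L))
    )),
    stop("unknown distractor class: ", class, call. = FALSE)
  )
}

# One citation line for the bibliography tail; the journal template with
# the bare "A <vol>" token is always included once per bibliography so that
# stripping it measurably removes false positives.
.bib_lines <- function(n_refs) {
  authors <- c("Smith", "Jones", "Tanaka", "Weber", "Olsen", "Garcia")
  lines <- vapply(seq_len(n_refs), function(i) {
    sprintf("%d. %s et al. J Membrane Physiol %d: %d-%d (%d).",
            i, sample(authors, 1L), sample(600:999, 1L),
            sample(100:199, 1L), sample(200:299, 1L), sample(1990:2020, 1L))
  }, character(1))
  anchor <- sprintf("%d. %s et al. Proc Natl Acad Sci U S A %d: %d-%d (%d).",
                    n_refs + 1L,
                    sample(authors, 1L), sample(600:999, 1L),
                    sample(100:199, 1L), sample(200:299, 1L),
                    sample(1990:2020, 1L))
  c(lines, anchor)
}

.random_mention <- function(form) {
  wt <- sample(.AA$one_letter, 1L)
  pos <- if (form == "single_digit") sample(1:9, 1L) else sample(10:400, 1L)
  mut <- NULL
  if (form %in% .MUTATION_FORMS) {
    mut <- sample(setdiff(.AA$one_letter, wt), 1L)
  }
  normalize_mention(wt, pos, mut)
}

#' Generate a synthetic annotated corpus
#'
#' Produces documents, the gold standard of planted mentions and a ledger
#' of planted distractor spans.  A single seeded pseudo-random stream
#' drives every choice, so identical configurations yield byte-identical
#' corpora; the caller's RNG state is left untouched.
#'
#' @param config A [corpus_config()].
#' @return An object of class `synthetic_corpus`: `documents` (named list
#'   of `rf_document`, each with `abstract`/`body` sections), `gold` (a
#'   `gold_standard` with per-key occurrence counts), `mention_ledger` and
#'   `distractor_ledger` (data frames of planted spans), and `config`.
#' @examples
#' corpus <- generate_corpus(corpus_config(n_docs = 2, seed = 42))
#' names(corpus$documents)
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  withr::with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(config) {
  docs <- vector("list", config$n_docs)
  gold <- vector("list", config$n_docs)
  mention_rows <- list()
  distractor_rows <- list()
  form_names <- names(config$form_mix)
  form_w <- config$form_mix
  dist_names <- names(config$distractor_mix)
  dist_w <- config$distractor_mix
  use_distractors <- length(dist_w) > 0 && sum(dist_w) > 0

  for (d in seq_len(config$n_docs)) {
    doc_id <- sprintf("synth%04d", d)
    n_m <- sample(config$mentions_per_doc[1]:config$mentions_per_doc[2], 1L)
    n_dist <- if (use_distractors) {
      sample(config$distractors_per_doc[1]:config$distractors_per_doc[2], 1L)
    } else 0L
    pieces <- list()
    if (n_m > 0L) {
      forms <- sample(form_names, n_m, replace = TRUE, prob = form_w)
      for (f in forms) {
        mention <- .random_mention(f)
        pieces[[length(pieces) + 1L]] <- list(
          kind = "mention", text = plant_form(mention, f),
          key = mention_key(mention), form = f
        )
      }
    }
    if (n_dist > 0L) {
      classes <- sample(dist_names, n_dist, replace = TRUE, prob = dist_w)
      for (cl in classes) {
        pieces[[length(pieces) + 1L]] <- list(
          kind = "distractor", text = .distractor_text(cl), class = cl
        )
      }
    }
    pieces <- pieces[sample.int(length(pieces))]

    # Assemble: a short abstract paragraph (filler + the first planted
    # piece), then the body with the remaining pieces woven into filler.
    buf <- character(0)
    offset <- 0L
    append_text <- function(txt) {
      buf <<- c(buf, txt)
      offset <<- offset + nchar(txt)
    }
    record_piece <- function(piece) {
      lead <- paste0(.filler_sentence(sample(4:9, 1L)), " ")
      append_text(lead)
      start <- offset
      append_text(piece$text)
      end <- offset
      append_text(paste0(" ", .filler_sentence(sample(3:7, 1L)), " "))
      if (piece$kind == "mention") {
        mention_rows[[length(mention_rows) + 1L]] <<- data.frame(
          doc_id = doc_id, start = start, end = end, key = piece$key,
          form = piece$form, stringsAsFactors = FALSE
        )
      } else {
        distractor_rows[[length(distractor_rows) + 1L]] <<- data.frame(
          doc_id = doc_id, start = start, end = end, class = piece$class,
          text = piece$text, stringsAsFactors = FALSE
        )
      }
    }

    n_abstract <- if (length(pieces) > 0L) min(1L, length(pieces)) else 0L
    for (i in seq_len(n_abstract)) record_piece(pieces[[i]])
    if (n_abstract == 0L) append_text(.filler_sentence(8L))
    abstract_end <- offset
    append_text("\n\n")
    if (length(pieces) > n_abstract) {
      for (i in (n_abstract + 1L):length(pieces)) record_piece(pieces[[i]])
    } else {
      append_text(.filler_sentence(10L))
    }
    bib <- if (config$include_bibliography) .bib_lines(sample(3:6, 1L))
           else character(0)
    if (length(bib) > 0L) {
      # pad the body so the References heading falls in the final half of
      # the text, where bibliography stripping looks for it
      bib_len <- sum(nchar(bib)) + length(bib) + nchar("\nReferences\n")
      while (offset < bib_len + 40L) {
        append_text(paste0(" ", .filler_sentence(sample(6:10, 1L))))
      }
    }
    body_end <- offset
    sections <- data.frame(
      section = c("abstract", "body"),
      start = c(0L, abstract_end),
      end = c(abstract_end, body_end),
      stringsAsFactors = FALSE
    )
    if (length(bib) > 0L) {
      append_text("\nReferences\n")
      bib_start <- offset
      for (line in bib) {
        append_text(paste0(line, "\n"))
      }
      sections <- rbind(sections, data.frame(
        section = "bibliography", start = bib_start, end = offset,
        stringsAsFactors = FALSE
      ))
    }
    text <- paste(buf, collapse = "")
    docs[[d]] <- document(doc_id, text, section_map = sections)
    keys <- vapply(Filter(function(p) p$kind == "mention", pieces),
                   `[[`, character(1), "key")
    gold[[d]] <- if (length(keys)) {
      tab <- table(keys)
      structure(as.integer(tab), names = names(tab))
    } else integer(0)
    names(docs)[d] <- doc_id
    names(gold)[d] <- doc_id
  }

  structure(list(
    documents = docs,
    gold = gold_standard(gold),
    mention_ledger = if (length(mention_rows)) do.call(rbind, mention_rows)
      else data.frame(doc_id = character(0), start = integer(0),
                      end = integer(0), key = character(0),
                      form = character(0), stringsAsFactors = FALSE),
    distractor_ledger = if (length(distractor_rows)) do.call(rbind, distractor_rows)
      else data.frame(doc_id = character(0), start = integer(0),
                      end = integer(0), class = character(0),
                      text = character(0), stringsAsFactors = FALSE),
    config = config
  ), class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d documents, %d planted mentions, %d distractors\n",
              length(x$documents), nrow(x$mention_ledger),
              nrow(x$distractor_ledger)))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Writes one `<doc_id>.txt` per document, the gold file (`gold.tsv`, see
#' [read_gold()]) and the distractor ledger (`distractors.tsv`).
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus$documents) {
    con <- file(file.path(dir, paste0(doc$doc_id, ".txt")), open = "wb")
    writeLines(enc2utf8(doc$text), con, sep = "\n", useBytes = TRUE)
    close(con)
  }
  write_gold(corpus$gold, file.path(dir, "gold.tsv"))
  led <- corpus$distractor_ledger
  lines <- c("doc_id\tstart\tend\tclass\ttext",
             sprintf("%s\t%d\t%d\t%s\t%s", led$doc_id, led$start, led$end,
                     led$class, led$text))
  con <- file(file.path(dir, "distractors.tsv"), open = "wb")
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(dir)
}
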