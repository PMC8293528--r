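# Normalized residue / mutation mention data model.
#
# A mention is a wild-type one-letter code plus a 1-based sequence position,
# optionally followed by a mutant one-letter code (point mutation, wNm
# nomenclature).  The canonical key renders as e.g. "S56" or "A64G".
# Positions are kept as digit strings so that arbitrarily long position
# tokens round-trip exactly; "0" and leading-zero tokens are rejected
# (protein numbering starts at 1, leading zeros are format noise).

.valid_pos_token <- function(pos) {
  is.character(pos) && length(pos) == 1L && grepl("^[1-9][0-9]*$", pos)
}

new_residue_mention <- function(wild_type, position, mutant = NA_character_) {
  structure(
    list(wild_type = wild_type, position = position, mutant = mutant),
    class = "residue_mention"
  )
}

#' Normalize tokens into a residue or mutation mention
#'
#' Builds the canonical in-memory representation of a residue mention
#' (wild-type identifier + position) or point-mutation mention (wild-type +
#' position + mutant).  Identifier tokens may be in one-letter, three-letter
#' or full-name form; the position may be any run of digits with no leading
#' zero, including single digits (positions near the start of a sequence are
#' real mentions, not noise).
#'
#' @param wt_token Wild-type residue identifier.
#' @param pos_token Sequence position as a digit string or whole number.
#' @param mut_token Optional mutant residue identifier.
#' @return An object of class `residue_mention`.
#' @examples
#' normalize_mention("Ser", "56")
#' normalize_mention("A", 64, "G")
#' mention_key(normalize_mention("G", "2"))
#' @export
normalize_mention <- function(wt_token, pos_token, mut_token = NULL) {
  wt <- to_one_letter(wt_token)
  if (is.numeric(pos_token) && length(pos_token) == 1L &&
      !is.na(pos_token) && pos_token == trunc(pos_token)) {
    pos_token <- format(pos_token, scientific = FALSE)
  }
  if (!.valid_pos_token(pos_token)) {
    stop(sprintf("invalid position token: \"%s\" (must be digits >= 1, no leading zero)",
                 as.character(pos_token)[1]), call. = FALSE)
  }
  mut <- NA_character_
  if (!is.null(mut_token) && !is.na(mut_token[1])) {
    mut <- to_one_letter(mut_token)
  }
  new_residue_mention(wt, pos_token, mut)
}

#' Canonical key of a mention
#'
#' @param mention A `residue_mention`.
#' @return A string such as `"S56"` or `"A64G"`.  A mutation mention and a
#'   residue mention at the same site have distinct keys.
#' @export
mention_key <- function(mention) {
  stopifnot(inherits(mention, "residue_mention"))
  paste0(mention$wild_type, mention$position,
         if (!is.na(mention$mutant)) mention$mutant else "")
}

#' Parse a canonical mention key
#'
#' Inverse of [mention_key()]: `"S56"` parses to a residue mention, `"A64G"`
#' to a mutation mention.
#'
#' @param key A mention key string.
#' @return A `residue_mention`.
#' @export
parse_mention_key <- function(key) {
  if (!is.character(key) || length(key) != 1L) {
    stop("`key` must be a single string", call. = FALSE)
  }
  m <- regexec("^([A-Z])([1-9][0-9]*)([A-Z])?$", key)
  parts <- regmatches(key, m)[[1]]
  if (length(parts) == 0L) {
    stop(sprintf("not a valid mention key: \"%s\"", key), call. = FALSE)
  }
  mut <- if (length(parts) >= 4L && nzchar(parts[4])) parts[4] else NULL
  normalize_mention(parts[2], parts[3], mut)
}

#' @export
print.residue_mention <- function(x, ...) {
  kind <- if (is.na(x$mutant)) "residue mention" else "mutation mention"
  cat(sprintf("<%s> %s\n", kind, mention_key(x)))
  invisible(x)
}

#' @export
format.residue_mention <- function(x, ...) mention_key(x)
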