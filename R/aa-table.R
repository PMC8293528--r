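# Canonical amino-acid nomenclature tables.  One-letter codes are the 20
# standard acids only; B/Z/X ambiguity codes and the non-canonical acids
# (selenocysteine, pyrrolysine) are deliberately excluded.

.AA <- data.frame(
  one_letter = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  three_letter = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                   "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                   "Thr", "Trp", "Tyr", "Val"),
  full_name = c("alanine", "arginine", "asparagine", "aspartic acid",
                "cysteine", "glutamine", "glutamic acid", "glycine",
                "histidine", "isoleucine", "leucine", "lysine", "methionine",
                "phenylalanine", "proline", "serine", "threonine",
                "tryptophan", "tyrosine", "valine"),
  stringsAsFactors = FALSE
)

# Accepted full-name synonyms (input only; canonical names live in .AA).
.AA_SYNONYMS <- c("aspartate" = "D", "glutamate" = "E")

#' Amino acid nomenclature table
#'
#' The 20 canonical amino acids with their one-letter code, three-letter code
#' and full common name.  The three columns are pairwise bijections; every
#' other function in the package normalizes residue identifiers through this
#' table.
#'
#' @return A data frame with columns `one_letter`, `three_letter` and
#'   `full_name`, one row per amino acid.
#' @examples
#' amino_acids()
#' @export
amino_acids <- function() {
  .AA
}

# Case policy for identifier recognition:
#   * one-letter codes: uppercase only ("S", never "s");
#   * three-letter codes: title case ("Ser") or all uppercase ("SER");
#   * full names: case-insensitive ("serine", "Serine", "SERINE").
# Returns the one-letter code or NA_character_ when the token is not a
# recognized identifier.
.aa_one_or_na <- function(token) {
  if (length(token) != 1L || is.na(token) || !nzchar(token)) {
    return(NA_character_)
  }
  if (nchar(token) == 1L) {
    if (token %in% .AA$one_letter) {
      return(token)
    }
    return(NA_character_)
  }
  if (nchar(token) == 3L) {
    hit <- match(token, .AA$three_letter)
    if (!is.na(hit)) {
      return(.AA$one_letter[hit])
    }
    hit <- match(token, toupper(.AA$three_letter))
    if (!is.na(hit)) {
      return(.AA$one_letter[hit])
    }
  }
  low <- tolower(token)
  hit <- match(low, .AA$full_name)
  if (!is.na(hit)) {
    return(.AA$one_letter[hit])
  }
  hit <- match(low, names(.AA_SYNONYMS))
  if (!is.na(hit)) {
    return(unname(.AA_SYNONYMS[hit]))
  }
  NA_character_
}

#' Convert a residue identifier to its one-letter code
#'
#' Accepts one-letter codes (uppercase only), three-letter codes (title case
#' or all uppercase) and full names (any case, including the synonyms
#' "aspartate" and "glutamate").
#'
#' @param token A single residue-identifier string.
#' @return The canonical one-letter code.
#' @examples
#' to_one_letter("Ser")
#' to_one_letter("serine")
#' to_one_letter("A")
#' @export
to_one_letter <- function(token) {
  if (!is.character(token) || length(token) != 1L) {
    stop("`token` must be a single character string", call. = FALSE)
  }
  code <- .aa_one_or_na(token)
  if (is.na(code)) {
    stop(sprintf("unrecognized residue identifier: \"%s\"", token),
         call. = FALSE)
  }
  code
}
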