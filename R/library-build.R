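# Generative construction of the shipped pattern libraries.
#
# The original residue/mutation libraries were distributed as flat pattern
# files; here every library is rebuilt from the nomenclature rules that
# define it, so the construction (and the lineage full -> cut) is explicit
# and auditable.  Library sizes match the published libraries: the full
# Regex 3 family has 1518 expressions, its cut version 6.
#
# Conventions shared by all generated expressions:
#   * named capture groups wt_res, pos and (for mutation patterns) mut_res;
#   * positions are [1-9][0-9]* -- single digits allowed, no leading zeros
#     (single-digit acceptance is toggled at extraction time, not here);
#   * guarded patterns require a non-alphanumeric character (or text
#     boundary) on both sides, expressed as fixed-width lookarounds so the
#     reported span covers only the mention itself;
#   * the bare capital-letter+number patterns of the Regex 3 family carry no
#     guards at all -- by design they fire on "T7", "C18", "H2O2" and
#     similar text, which is the documented precision cost of that library.

.AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"

.LGUARD <- "(?<![A-Za-z0-9])"
.RGUARD <- "(?![A-Za-z0-9])"

.aa_alt <- function(form) {
  aa <- .AA
  switch(form,
    one        = sprintf("[%s]", .AA_ALPHABET),
    three      = sprintf("(?:%s)", paste(aa$three_letter, collapse = "|")),
    threeupper = sprintf("(?:%s)", paste(toupper(aa$three_letter), collapse = "|")),
    full       = sprintf("(?i:%s)",
                         paste(c(aa$full_name, names(.AA_SYNONYMS)), collapse = "|")),
    stop("unknown identifier form: ", form)
  )
}

.grp <- function(name, alt) sprintf("(?P<%s>%s)", name, alt)

.POS <- "(?P<pos>[1-9][0-9]*)"

.IDENT_FORMS <- c("one", "three", "threeupper", "full")

.new_entries <- function(pattern_id, expression, provenance, cut,
                         case_sensitive = TRUE) {
  data.frame(pattern_id = pattern_id, expression = expression,
             case_sensitive = case_sensitive, provenance = provenance,
             cut = cut, stringsAsFactors = FALSE)
}

# Core residue patterns: identifier (4 forms) x separator (none / one
# space), mutant identifier of the same form optional.  The no-space
# entries form the Regex 1 layer; the spaced entries are the Regex 2
# additions.  Cut membership: {one-letter, three-letter title-case,
# full-name} x {no space, space} -- the six most common nomenclatures.
.build_core_entries <- function() {
  rows <- list()
  for (form in .IDENT_FORMS) {
    for (sep in c("nospace", "space")) {
      w <- .grp("wt_res", .aa_alt(form))
      m <- sprintf("%s?", .grp("mut_res", .aa_alt(form)))
      sp <- if (sep == "space") " " else ""
      expr <- paste0(.LGUARD, w, sp, .POS, m, .RGUARD)
      rows[[length(rows) + 1L]] <- .new_entries(
        pattern_id = sprintf("res_%s_%s", form, sep),
        expression = expr,
        provenance = if (sep == "nospace") "rf1" else "rf2",
        cut = form %in% c("one", "three", "full")
      )
    }
  }
  do.call(rbind, rows)
}

# Mutation-only patterns (mutant identifier required, no space): the
# mutation-finder lineage.  Cut membership: the wNm one-letter and
# three-letter forms, which dominate real usage.
.build_mf_entries <- function() {
  rows <- lapply(.IDENT_FORMS, function(form) {
    w <- .grp("wt_res", .aa_alt(form))
    m <- .grp("mut_res", .aa_alt(form))
    .new_entries(
      pattern_id = sprintf("mut_%s_nospace", form),
      expression = paste0(.LGUARD, w, .POS, m, .RGUARD),
      provenance = "mf",
      cut = form %in% c("one", "three")
    )
  })
  do.call(rbind, rows)
}

# Regex 3 structural extras: bare capital+number (no context guards; the
# capital is still restricted to the 20-acid alphabet), a bare wNm variant,
# PDF-conversion junk tolerance (one stray non-alphanumeric character
# between identifier and position), and arrow-notation mutations.
.build_rf3_extras <- function() {
  one <- .aa_alt("one")
  rows <- list(
    .new_entries("x_bare", paste0(.grp("wt_res", one), .POS), "rf3", FALSE),
    .new_entries("x_bare_mut",
                 paste0(.grp("wt_res", one), .POS, .grp("mut_res", one)),
                 "rf3", FALSE)
  )
  junk <- "[^A-Za-z0-9\\s]"
  for (form in .IDENT_FORMS) {
    rows[[length(rows) + 1L]] <- .new_entries(
      pattern_id = sprintf("x_junk_%s", form),
      expression = paste0(.LGUARD, .grp("wt_res", .aa_alt(form)),
                          junk, " ?", .POS, .RGUARD),
      provenance = "rf3", cut = FALSE
    )
  }
  arrow <- "(?:→|-->|->|⇒)"
  mut_alt <- sprintf("(?:%s|%s)", one, .aa_alt("three"))
  for (form in .IDENT_FORMS) {
    rows[[length(rows) + 1L]] <- .new_entries(
      pattern_id = sprintf("x_arrow_%s", form),
      expression = paste0(.LGUARD, .grp("wt_res", .aa_alt(form)), .POS,
                          " ?", arrow, " ?", .grp("mut_res", mut_alt), .RGUARD),
      provenance = "rf3", cut = FALSE
    )
  }
  do.call(rbind, rows)
}

# Natural-language mutation frames.  Each frame is instantiated for the six
# substitution verbs and all 16 wild-type x mutant identifier-form pairs
# (mixed forms such as "S56 was mutated to alanine" occur in real text).
# Leading fixed literal context is placed in a lookbehind so the reported
# span starts at the first mention token; that makes a frame hit collapse
# with the plain-pattern hit at the same offset instead of double counting.
.NL_VERBS <- list(
  c(past = "mutated",     noun = "mutation"),
  c(past = "substituted", noun = "substitution"),
  c(past = "replaced",    noun = "replacement"),
  c(past = "changed",     noun = "change"),
  c(past = "converted",   noun = "conversion"),
  c(past = "exchanged",   noun = "exchange")
)

# Frame templates: {W} wild-type group, {P} position group, {M} mutant
# group, {Vp}/{Vn} verb past/noun, {B}/{E} boundary guards.
.NL_MUT_FRAMES <- c(
  "{B}{W}{P} was {Vp} to {M}{E}",
  "{B}{W}{P} was {Vp} by {M}{E}",
  "{B}{W}{P} was {Vp} with {M}{E}",
  "{B}{W}{P} was {Vp} into {M}{E}",
  "{B}{W}{P} {Vp} to {M}{E}",
  "{B}{W} {P} was {Vp} to {M}{E}",
  "{B}{W} at position {P} was {Vp} to {M}{E}",
  "{B}{W} at position {P} was {Vp} by {M}{E}",
  "(?<={Vn} of ){W}{P} to {M}{E}",
  "(?<={Vn} of ){W}{P} by {M}{E}",
  "(?<={Vn} of ){W}{P} with {M}{E}",
  "(?<={Vn} of ){W} {P} to {M}{E}",
  "(?<={Vn} of ){W} at position {P} to {M}{E}",
  "{B}{M} was {Vp} for {W}{P}{E}",
  "{B}{W}{P} to {M}(?= {Vn})"
)

# Residue context frames: redundant with the core patterns on purpose (the
# shipped libraries are heavily redundant); all context is in lookarounds,
# so these hits always share a span start with a core-pattern hit.
.NL_RES_FRAMES <- c(
  "(?<=residue ){C}",
  "(?<=amino acid ){C}",
  "{C}(?= residue)",
  "{C}(?= side chain)",
  "(?<=position ){C}",
  "(?<=at ){C}",
  "(?<=the ){C}(?= residue)",
  "{C}(?= site)",
  "(?<=mutant ){C}",
  "(?<=residues ){C}",
  "(?<=of ){C}",
  "(?<=in ){C}",
  "{C}(?= position)",
  "{C}(?= mutant)",
  "{C}(?= and )"
)

.fill <- function(template, subst) {
  for (key in names(subst)) {
    template <- gsub(key, subst[[key]], template, fixed = TRUE)
  }
  template
}

.build_nl_entries <- function() {
  rows <- vector("list", 1500L)
  k <- 0L
  for (vi in seq_along(.NL_VERBS)) {
    verb <- .NL_VERBS[[vi]]
    for (fi in seq_along(.NL_MUT_FRAMES)) {
      for (wf in .IDENT_FORMS) {
        for (mf in .IDENT_FORMS) {
          expr <- .fill(.NL_MUT_FRAMES[[fi]], list(
            "{B}" = .LGUARD, "{E}" = .RGUARD,
            "{W}" = .grp("wt_res", .aa_alt(wf)),
            "{M}" = .grp("mut_res", .aa_alt(mf)),
            "{P}" = .POS,
            "{Vp}" = verb[["past"]], "{Vn}" = verb[["noun"]]
          ))
          k <- k + 1L
          rows[[k]] <- .new_entries(
            pattern_id = sprintf("nl_mut_v%df%02d_%s_%s", vi, fi, wf, mf),
            expression = expr, provenance = "rf3", cut = FALSE
          )
        }
      }
    }
  }
  for (fi in seq_along(.NL_RES_FRAMES)) {
    for (wf in .IDENT_FORMS) {
      core <- paste0(.LGUARD, .grp("wt_res", .aa_alt(wf)), .POS, .RGUARD)
      expr <- .fill(.NL_RES_FRAMES[[fi]], list("{C}" = core))
      k <- k + 1L
      rows[[k]] <- .new_entries(
        pattern_id = sprintf("nl_res_f%02d_%s", fi, wf),
        expression = expr, provenance = "rf3", cut = FALSE
      )
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

# Full entry tables, built once per session.
.build_all_rf_entries <- function() {
  rbind(.build_core_entries(), .build_rf3_extras(), .build_nl_entries())
}
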