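#' Default protein-altering effect terms
#'
#' Sequence-Ontology-style effect terms treated as protein-coding by
#' [classify_consequence()]. Splice-site terms are grouped with the
#' protein-coding class because splice-disrupting lesions abolish the
#' protein product just as coding changes can; the set is user-overridable.
#'
#' @export
protein_coding_terms <- c(
  "missense_variant", "stop_gained", "stop_lost", "start_lost",
  "synonymous_variant", "frameshift_variant", "inframe_insertion",
  "inframe_deletion", "splice_donor_variant", "splice_acceptor_variant"
)

#' Classify a variant's functional consequence
#'
#' Triage of annotation entries into the coarse consequence classes used to
#' prioritize pattern-matching survivors: `protein_coding` if any entry
#' carries a protein-altering effect term, else `intronic` if any entry is
#' an `intron_variant`, else `intergenic` if all entries are intergenic (or
#' there are no annotations at all), else `other`. The precedence
#' protein_coding > intronic > intergenic > other means the most severe
#' transcript annotation wins when several transcripts annotate one site,
#' and the result does not depend on entry order.
#'
#' @param ann An annotation tibble as returned by [parse_ann()] (zero rows
#'   means unannotated).
#' @param coding_terms Character vector of effect terms counted as
#'   protein-coding; defaults to [protein_coding_terms].
#' @return One of `"protein_coding"`, `"intronic"`, `"intergenic"`,
#'   `"other"`.
#' @export
classify_consequence <- function(ann, coding_terms = protein_coding_terms) {
  if (is.null(ann) || nrow(ann) == 0) return("intergenic")
  terms <- unlist(ann$effect)
  if (any(terms %in% coding_terms)) return("protein_coding")
  if (any(terms == "intron_variant")) return("intronic")
  if (all(terms %in% c("intergenic_region", "intergenic_variant"))) {
    return("intergenic")
  }
  "other"
}

#' Parse an HGVS coding-substitution description
#'
#' Parses a simple coding-sequence substitution in HGVS `c.` notation
#' (`c.<pos><ref>><alt>`, whitespace around `>` tolerated) and derives its
#' codon coordinates: `codon_index = floor((pos - 1)/3) + 1` is the affected
#' amino-acid position, and `within_codon_offset` (1, 2 or 3) is the changed
#' base's position inside that codon. Intronic offsets (`c.123+5G>A`),
#' UTR positions (`c.-12`, `c.*33`) and indels are outside the substitution
#' grammar and raise an explicit unsupported-notation error.
#'
#' @param text An HGVS `c.` substitution string, e.g. `"c.1678C>T"`.
#' @return A one-row tibble with columns `cds_pos`, `ref_base`, `alt_base`,
#'   `codon_index`, `within_codon_offset`.
#' @examples
#' parse_hgvs_c("c.1678C>T")  # codon 560, first base of the codon
#' @export
parse_hgvs_c <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  m <- stringr::str_match(stringr::str_trim(text),
                          "^c\\.([0-9]+)([ACGT])\\s*>\\s*([ACGT])$")
  if (is.na(m[1, 1])) {
    abort(sprintf(
      "unsupported HGVS c. notation '%s': only simple coding substitutions c.<pos><ref>><alt> are handled (no intronic offsets, UTR positions or indels)",
      text))
  }
  cds_pos <- as.integer(m[1, 2])
  if (cds_pos < 1) abort("HGVS c. position must be >= 1")
  if (m[1, 3] == m[1, 4]) {
    abort(sprintf("'%s' is not a substitution: reference and alternate base are identical", text))
  }
  tibble(
    cds_pos = cds_pos,
    ref_base = m[1, 3],
    alt_base = m[1, 4],
    codon_index = (cds_pos - 1L) %/% 3L + 1L,
    within_codon_offset = (cds_pos - 1L) %% 3L + 1L
  )
}

#' Predict the amino-acid change of a coding substitution
#'
#' Applies a parsed coding substitution to its reference codon, translates
#' both codons under the standard genetic code, and categorizes the change.
#' The stated reference base must match the codon at the substitution's
#' within-codon offset; a mismatch raises an inconsistency error — this is
#' the validation used to check that a reported `c.` description and the
#' protein-level consequence are mutually consistent.
#'
#' @param ref_codon Three uppercase DNA bases (the reference codon).
#' @param change A one-row tibble from [parse_hgvs_c()].
#' @return A one-row tibble with columns `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa` (single-letter, `*` for stop) and `category` (`missense`,
#'   `synonymous`, `nonsense`, `stop_lost`).
#' @examples
#' predict_aa_change("CGC", parse_hgvs_c("c.1678C>T"))  # Arg -> Cys
#' @export
predict_aa_change <- function(ref_codon, change) {
  stopifnot(is.character(ref_codon), length(ref_codon) == 1)
  if (!grepl("^[ACGT]{3}$", ref_codon)) {
    abort(sprintf("'%s' is not a valid uppercase DNA codon", ref_codon))
  }
  off <- change$within_codon_offset
  if (substr(ref_codon, off, off) != change$ref_base) {
    abort(sprintf(
      "inconsistency: reference codon %s has '%s' at codon position %d, but the coding change states reference base '%s'",
      ref_codon, substr(ref_codon, off, off), off, change$ref_base))
  }
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- change$alt_base
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  category <- if (ref_aa == alt_aa) {
    "synonymous"
  } else if (alt_aa == "*") {
    "nonsense"
  } else if (ref_aa == "*") {
    "stop_lost"
  } else {
    "missense"
  }
  tibble(ref_codon = ref_codon, alt_codon = alt_codon,
         ref_aa = ref_aa, alt_aa = alt_aa, category = category)
}

# Protein position printed in an HGVS p. description ("p.Arg560Cys",
# "p.R560C"), or NA if none can be extracted.
hgvs_p_position <- function(hgvs_p) {
  pos <- suppressWarnings(as.integer(stringr::str_match(
    hgvs_p, "^p\\.\\(?[A-Za-z*]{1,3}([0-9]+)")[, 2]))
  pos
}
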