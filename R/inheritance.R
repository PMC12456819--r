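#' Define an inheritance model
#'
#' An inheritance model maps affection status to the set of genotype classes
#' each individual must carry for a variant to fit the model. Two built-in
#' models cover the standard situation where a subset of a carrier family
#' expresses a phenotype:
#'
#' * `het_carrier_hom_affected` — affected individuals are homozygous for the
#'   alternate allele, unaffected individuals are heterozygous carriers
#'   (a recessive variant segregating in a carrier-by-homozygote cross).
#' * `wt_carrier_het_affected` — affected individuals are heterozygous,
#'   unaffected individuals are homozygous reference (a dominant or
#'   haploinsufficient candidate).
#'
#' User-defined models supply `required` directly.
#'
#' @param model Built-in model id, or an arbitrary label when `required` is
#'   given.
#' @param required Optional named list with elements `affected` and
#'   `unaffected`, each a character vector of genotype classes from
#'   `hom_ref`, `het`, `hom_alt`.
#' @param missing_policy How a missing genotype call among required members
#'   is treated during filtering: `"strict"` (any missing call rejects the
#'   variant) or `"ignore_sample"` (the member is dropped from the
#'   requirement for that variant).
#' @return An `inheritance_model` object.
#' @examples
#' inheritance_model("het_carrier_hom_affected")
#' inheritance_model("custom_dominant",
#'   required = list(affected = c("het", "hom_alt"), unaffected = "hom_ref"))
#' @export
inheritance_model <- function(model, required = NULL,
                              missing_policy = c("strict", "ignore_sample")) {
  missing_policy <- match.arg(missing_policy)
  builtin <- list(
    het_carrier_hom_affected = list(affected = "hom_alt", unaffected = "het"),
    wt_carrier_het_affected = list(affected = "het", unaffected = "hom_ref")
  )
  if (is.null(required)) {
    if (!model %in% names(builtin)) {
      abort(sprintf(
        "unknown model '%s'; built-ins are %s (or supply `required`)",
        model, paste(names(builtin), collapse = ", ")))
    }
    required <- builtin[[model]]
  }
  if (!all(c("affected", "unaffected") %in% names(required))) {
    abort("`required` must define both 'affected' and 'unaffected'")
  }
  required <- lapply(required[c("affected", "unaffected")], as.character)
  bad <- setdiff(unlist(required), GT_INFORMATIVE)
  if (length(bad) > 0) {
    abort(paste0("unknown genotype class(es) in `required`: ",
                 paste(bad, collapse = ", ")))
  }
  if (any(lengths(required) == 0)) {
    abort("`required` sets must be non-empty for both affection states")
  }
  if (length(intersect(required$affected, required$unaffected)) > 0) {
    warn(paste0(
      "required genotype classes for affected and unaffected overlap; ",
      "the model cannot reject variants on the shared class(es)"))
  }
  structure(
    list(model_id = model, required = required,
         missing_policy = missing_policy),
    class = "inheritance_model"
  )
}

#' @export
print.inheritance_model <- function(x, ...) {
  cat(sprintf("<inheritance_model> %s\n", x$model_id))
  cat(sprintf("  affected   -> {%s}\n", paste(x$required$affected, collapse = ", ")))
  cat(sprintf("  unaffected -> {%s}\n", paste(x$required$unaffected, collapse = ", ")))
  cat(sprintf("  missing policy: %s\n", x$missing_policy))
  invisible(x)
}

as_inheritance_model <- function(model) {
  if (inherits(model, "inheritance_model")) model else inheritance_model(model)
}

#' Derive per-member genotype requirements under a model
#'
#' Maps every sequenced pedigree member with known affection status to the
#' set of genotype classes the inheritance model requires of them. Members
#' with unknown affection cannot constrain the filter; they are excluded and
#' reported via the `excluded` attribute (and a message).
#'
#' @param pedigree A `pedigree` tibble.
#' @param model An `inheritance_model` or built-in model id.
#' @return A tibble with columns `member_id`, `affection` and `required`
#'   (a list-column of genotype-class character vectors), one row per
#'   sequenced member with known affection, in pedigree order. Attribute
#'   `excluded` lists sequenced members skipped for unknown affection.
#' @export
derive_requirements <- function(pedigree, model) {
  model <- as_inheritance_model(model)
  seq_members <- pedigree[pedigree$sequenced, ]
  if (nrow(seq_members) == 0) {
    abort("pedigree has no sequenced members; the filter has no constraints")
  }
  excluded <- seq_members$member_id[seq_members$affection == "unknown"]
  if (length(excluded) > 0) {
    inform(paste0("excluding member(s) with unknown affection: ",
                  paste(excluded, collapse = ", ")))
  }
  known <- seq_members[seq_members$affection != "unknown", ]
  out <- tibble(
    member_id = known$member_id,
    affection = known$affection,
    required = unname(model$required[known$affection])
  )
  attr(out, "excluded") <- excluded
  attr(out, "model_id") <- model$model_id
  out
}
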