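EXCLUSION_REASONS <- c("missing-genotype", "other-class", "pattern-mismatch")

# Vectorized pattern matcher over a genotype-class matrix (variants x
# members). Returns pass/fail plus the first failing member's reason, with
# members evaluated in requirement order.
match_requirements <- function(class_matrix, requirements,
                               missing_policy = "strict",
                               max_discordant = 0L) {
  members <- requirements$member_id
  absent <- setdiff(members, colnames(class_matrix))
  if (length(absent) > 0) {
    abort(paste0("required member(s) absent from the genotype data: ",
                 paste(absent, collapse = ", ")))
  }
  n <- nrow(class_matrix)
  m <- length(members)
  fail <- matrix(FALSE, n, m)
  reason <- matrix(NA_character_, n, m)
  considered <- matrix(TRUE, n, m)  # FALSE = dropped under ignore_sample
  for (j in seq_len(m)) {
    cls <- class_matrix[, members[j]]
    in_set <- cls %in% requirements$required[[j]]
    is_missing <- cls == "missing"
    is_other <- cls == "other"
    if (missing_policy == "ignore_sample") {
      considered[, j] <- !is_missing
      fail[, j] <- !is_missing & (is_other | !in_set)
    } else {
      fail[, j] <- is_missing | is_other | !in_set
    }
    reason[fail[, j] & is_missing, j] <- "missing-genotype"
    reason[fail[, j] & is_other, j] <- "other-class"
    reason[fail[, j] & is.na(reason[, j]), j] <- "pattern-mismatch"
  }
  n_fail <- rowSums(fail)
  all_dropped <- rowSums(considered) == 0
  pass <- n_fail <= max_discordant & !all_dropped
  first_reason <- rep(NA_character_, n)
  any_fail <- n_fail > 0
  if (any(any_fail)) {
    first_idx <- max.col(fail, ties.method = "first")
    first_reason[any_fail] <- reason[cbind(which(any_fail),
                                           first_idx[any_fail])]
  }
  first_reason[!pass & all_dropped] <- "missing-genotype"
  first_reason[pass] <- NA_character_
  list(pass = pass, reason = first_reason, n_discordant = n_fail)
}

#' Test whether one variant's genotypes fit an inheritance model
#'
#' Exact-match test of a single variant's per-member genotype classes
#' against the per-member requirement sets from [derive_requirements()].
#' Under `missing_policy = "strict"` any missing or `other` call among the
#' required members rejects the variant; under `"ignore_sample"` missing
#' members are dropped from the requirement (a variant with all required
#' members missing is still rejected).
#'
#' @param genotypes Named character vector of genotype classes, keyed by
#'   member id (a superset of the required members).
#' @param requirements Requirement tibble from [derive_requirements()].
#' @param missing_policy `"strict"` or `"ignore_sample"`.
#' @param max_discordant Number of discordant members tolerated before
#'   rejection (0 = exact match).
#' @return A list with `match` (logical) and `reason` (`NA` on a match,
#'   otherwise the first failure among `missing-genotype`, `other-class`,
#'   `pattern-mismatch`).
#' @export
matches_model <- function(genotypes, requirements,
                          missing_policy = c("strict", "ignore_sample"),
                          max_discordant = 0L) {
  missing_policy <- match.arg(missing_policy)
  mat <- matrix(genotypes, nrow = 1,
                dimnames = list(NULL, names(genotypes)))
  res <- match_requirements(mat, requirements, missing_policy,
                            max_discordant)
  list(match = res$pass[1], reason = res$reason[1])
}

#' Filter variants by cosegregation with an inheritance model
#'
#' The core pattern-matching step: every variant whose genotype classes at
#' the sequenced pedigree members exactly fit the inheritance model's
#' requirements survives; every other variant is excluded and tallied by
#' the reason of its first failure. Surviving variants are triaged into
#' consequence classes from their annotations.
#'
#' @param variants A `variant_tbl` from [read_vcf()] or
#'   [simulate_cosegregation()].
#' @param pedigree A `pedigree` tibble; its sequenced members must all be
#'   present among the variant table's samples.
#' @param model An `inheritance_model` or built-in model id.
#' @param missing_policy Overrides the model's missing policy when given.
#' @param max_discordant Number of discordant members tolerated (default 0,
#'   exact match).
#' @param coding_terms Effect terms counted as protein-coding during triage.
#' @return A `segregation_result` object: a list with `model_id`,
#'   `surviving` (the surviving rows, input order preserved, plus a
#'   `consequence` column), `n_input`, `n_surviving`, `per_class_counts`,
#'   `exclusions`, `requirements` and `missing_policy`. Use [tidy()] for
#'   the surviving variants and [glance()] for the one-row summary.
#' @export
segregate <- function(variants, pedigree, model,
                      missing_policy = NULL, max_discordant = 0L,
                      coding_terms = protein_coding_terms) {
  model <- as_inheritance_model(model)
  missing_policy <- missing_policy %||% model$missing_policy
  missing_policy <- match.arg(missing_policy, c("strict", "ignore_sample"))
  requirements <- derive_requirements(pedigree, model)
  samples <- vcf_samples(variants)
  absent <- setdiff(requirements$member_id, samples)
  if (length(absent) > 0) {
    abort(paste0("sequenced pedigree member(s) missing from the VCF samples: ",
                 paste(absent, collapse = ", ")))
  }
  n <- nrow(variants)
  if (n == 0) {
    mat <- matrix(character(), 0, length(samples),
                  dimnames = list(NULL, samples))
  } else {
    mat <- as.matrix(as.data.frame(variants[, samples, drop = FALSE]))
  }
  res <- match_requirements(mat, requirements, missing_policy,
                            max_discordant)
  surviving <- variants[res$pass, , drop = FALSE]
  surviving$consequence <- vapply(surviving$ann, classify_consequence,
                                  character(1), coding_terms = coding_terms)
  per_class <- table(factor(surviving$consequence,
                            levels = c("protein_coding", "intronic",
                                       "intergenic", "other")))
  exclusions <- table(factor(res$reason[!res$pass],
                             levels = EXCLUSION_REASONS))
  structure(
    list(model_id = model$model_id,
         surviving = surviving,
         n_input = n,
         n_surviving = nrow(surviving),
         per_class_counts = setNames(as.integer(per_class),
                                     names(per_class)),
         exclusions = setNames(as.integer(exclusions), names(exclusions)),
         requirements = requirements,
         missing_policy = missing_policy,
         max_discordant = max_discordant),
    class = "segregation_result"
  )
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("<segregation_result> model %s (%s policy)\n",
              x$model_id, x$missing_policy))
  cat(sprintf("  %d variants in -> %d fit the pattern\n",
              x$n_input, x$n_surviving))
  cat("  survivors by consequence: ",
      paste(sprintf("%s %d", names(x$per_class_counts), x$per_class_counts),
            collapse = ", "), "\n", sep = "")
  cat("  exclusions: ",
      paste(sprintf("%s %d", names(x$exclusions), x$exclusions),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn segregate Surviving variants as a tibble (one row per
#'   surviving site, with its consequence class).
#' @param x A `segregation_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.segregation_result <- function(x, ...) {
  out <- as_tibble(x$surviving)
  out$model_id <- x$model_id
  gene <- vapply(out$ann, function(a) {
    if (nrow(a) == 0) NA_character_ else a$gene[1]
  }, character(1))
  out$gene <- gene
  dplyr::relocate(out, "model_id", "site_id", "consequence", "gene")
}

#' @describeIn segregate One-row summary (input size, survivor count,
#'   consequence-class and exclusion-reason tallies).
#' @exportS3Method generics::glance
glance.segregation_result <- function(x, ...) {
  tibble(
    model_id = x$model_id,
    n_input = x$n_input,
    n_surviving = x$n_surviving,
    n_protein_coding = x$per_class_counts[["protein_coding"]],
    n_intronic = x$per_class_counts[["intronic"]],
    n_intergenic = x$per_class_counts[["intergenic"]],
    n_other_class = x$per_class_counts[["other"]],
    n_excl_missing = x$exclusions[["missing-genotype"]],
    n_excl_other = x$exclusions[["other-class"]],
    n_excl_mismatch = x$exclusions[["pattern-mismatch"]],
    missing_policy = x$missing_policy
  )
}

#' Plot the variant-filtering flow of a segregation result
#'
#' Bar chart of where the input variants went: exclusion reasons on one
#' side, surviving variants broken down by consequence class on the other —
#' a graphical rendering of the filtering flowchart.
#'
#' @param object A `segregation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.segregation_result <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(stage = "excluded", group = names(object$exclusions),
           n = object$exclusions),
    tibble(stage = "surviving", group = names(object$per_class_counts),
           n = object$per_class_counts)
  )
  df <- df[df$n > 0 | df$stage == "surviving", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$n,
                                   fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~stage, scales = "free_x", space = "free_x") +
    ggplot2::labs(
      title = sprintf("Model %s: %d variants in, %d fit the pattern",
                      object$model_id, object$n_input, object$n_surviving),
      x = NULL, y = "variants") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Expected survival probability of a neutral variant
#'
#' Closed-form probability that a neutral site passes a genotype-pattern
#' requirement, assuming genotypes independent across individuals and
#' Hardy–Weinberg proportions at alternate-allele frequency `q`:
#' \deqn{(q^2)^a \, (2q(1-q))^h \, ((1-q)^2)^r} for `a` individuals required
#' homozygous-alternate, `h` required heterozygous and `r` required
#' homozygous-reference. Within a pedigree, transmission correlates
#' genotypes across relatives, so this expectation applies to an unrelated
#' panel (the simulator's `unrelated_panel` mode), where it calibrates the
#' filter's false-positive behaviour.
#'
#' @param allele_freq Alternate-allele frequency `q`, strictly inside (0, 1).
#'   Vectorized.
#' @param n_hom_alt,n_het,n_hom_ref Numbers of individuals required in each
#'   genotype class (at least one must be positive).
#' @return Numeric vector of survival probabilities.
#' @examples
#' expected_null_survival(0.5, n_hom_alt = 1, n_het = 1)  # 0.125
#' @export
expected_null_survival <- function(allele_freq, n_hom_alt = 0L, n_het = 0L,
                                   n_hom_ref = 0L) {
  if (any(allele_freq <= 0 | allele_freq >= 1)) {
    abort("allele_freq must be strictly inside (0, 1)")
  }
  if (n_hom_alt < 0 || n_het < 0 || n_hom_ref < 0 ||
      n_hom_alt + n_het + n_hom_ref == 0) {
    abort("requirement counts must be non-negative with at least one positive")
  }
  q <- allele_freq
  (q^2)^n_hom_alt * (2 * q * (1 - q))^n_het * ((1 - q)^2)^n_hom_ref
}
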