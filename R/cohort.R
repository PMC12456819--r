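#' Read a confirmation-cohort genotype/phenotype table
#'
#' Reads a TSV or CSV table (header required) describing an independent
#' cohort genotyped at a candidate locus and phenotyped. Required columns:
#' `id`, `genotype`, `phenotype`. Genotypes may be encoded as class names
#' (`hom_ref`/`het`/`hom_alt`), alternate-allele dosage (`0`/`1`/`2`), or
#' allele-pair strings (e.g. `rd10/rd10`, `rd10/+`, `+/+`), which are
#' normalized: a pair of identical wild-type alleles (`+`, `wt`, `ref`) is
#' `hom_ref`, a pair of identical mutant alleles is `hom_alt`, a mixed pair
#' is `het`. Rows whose genotype cannot be parsed are excluded with a
#' message and counted in the `n_excluded` attribute.
#'
#' @param path Path to the cohort table (delimiter inferred from content:
#'   tab if present in the header line, else comma).
#' @return A tibble with columns `animal_id`, `genotype`
#'   (`hom_ref`/`het`/`hom_alt`) and `phenotype`
#'   (`affected`/`unaffected`), attribute `n_excluded`.
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  needed <- c("id", "genotype", "phenotype")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  genotype <- normalize_cohort_genotype(raw$genotype)
  phenotype <- normalize_cohort_phenotype(raw$phenotype)
  keep <- !is.na(genotype) & !is.na(phenotype)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    inform(sprintf("excluded %d cohort row(s) with unparseable genotype or phenotype",
                   n_excluded))
  }
  out <- tibble(animal_id = raw$id[keep], genotype = genotype[keep],
                phenotype = phenotype[keep])
  attr(out, "n_excluded") <- n_excluded
  out
}

WT_ALLELE_TOKENS <- c("+", "wt", "ref")

normalize_cohort_genotype <- function(x) {
  x <- stringr::str_trim(x)
  vapply(x, function(g) {
    gl <- tolower(g)
    if (gl %in% c("hom_ref", "het", "hom_alt")) return(gl)
    if (g %in% c("0", "1", "2")) {
      return(c("hom_ref", "het", "hom_alt")[as.integer(g) + 1L])
    }
    if (grepl("/", g, fixed = TRUE)) {
      alleles <- tolower(stringr::str_trim(strsplit(g, "/", fixed = TRUE)[[1]]))
      if (length(alleles) == 2 && all(nzchar(alleles))) {
        wt <- alleles %in% WT_ALLELE_TOKENS
        if (sum(wt) == 1) return("het")
        if (all(wt)) return("hom_ref")
        if (alleles[1] == alleles[2]) return("hom_alt")
        return("het")
      }
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

normalize_cohort_phenotype <- function(x) {
  dplyr::case_match(tolower(stringr::str_trim(x)),
                    c("affected", "2", "yes", "rd", "case") ~ "affected",
                    c("unaffected", "1", "no", "control") ~ "unaffected",
                    .default = NA_character_)
}

# One-sided exact hypergeometric tail: probability, under random assignment
# of the K carrier genotypes to the n affected slots among N animals, that
# at least x affected animals are carriers. Written from the closed form
# sum_{k >= x} C(K,k) C(N-K, n-k) / C(N,n).
hypergeom_tail <- function(x, K, N, n) {
  ks <- seq(max(x, 0L, n - (N - K)), min(K, n))
  if (length(ks) == 0) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

#' Genotype-phenotype concordance of a candidate variant in a cohort
#'
#' Summarizes how well a candidate variant cosegregates with a phenotype in
#' an independent cohort under the recessive reading (affected if and only
#' if homozygous for the alternate allele). Reports the 2x2 table of
#' [homozygous-alternate vs not] against [affected vs unaffected], the
#' discordant count (affected non-homozygotes plus unaffected homozygotes;
#' unaffected carriers and unaffected homozygous-reference animals are both
#' concordant), and a one-sided exact hypergeometric p-value: the
#' probability, when the observed genotype margin is assigned at random to
#' the observed phenotype margin, of at least as many affected homozygotes
#' as observed. The descriptive counts are the primary readout; the exact
#' test gives imperfect cohorts a quantitative measure.
#'
#' @param records Cohort tibble from [read_cohort()] (or any data frame
#'   with `genotype` and `phenotype` columns in the same encoding).
#' @return A `concordance_summary` object; see [tidy()] for the 2x2 table
#'   and [glance()] for the one-row summary with `p_one_sided`.
#' @export
concordance <- function(records) {
  if (nrow(records) == 0) abort("cohort has no records")
  hom <- records$genotype == "hom_alt"
  aff <- records$phenotype == "affected"
  tab <- matrix(c(sum(hom & aff), sum(hom & !aff),
                  sum(!hom & aff), sum(!hom & !aff)),
                nrow = 2, byrow = TRUE,
                dimnames = list(genotype = c("hom_alt", "not_hom_alt"),
                                phenotype = c("affected", "unaffected")))
  n_total <- nrow(records)
  degenerate <- all(aff) || all(!aff)
  if (degenerate) {
    warn("cohort has a single phenotype class; concordance p-value is undefined and reported as 1")
    p <- 1
  } else {
    p <- hypergeom_tail(x = tab["hom_alt", "affected"],
                        K = sum(hom), N = n_total, n = sum(aff))
  }
  structure(
    list(
      n_total = n_total,
      n_affected_hom_alt = sum(aff & hom),
      n_unaffected_het = sum(!aff & records$genotype == "het"),
      n_unaffected_hom_ref = sum(!aff & records$genotype == "hom_ref"),
      n_discordant = sum(aff & !hom) + sum(!aff & hom),
      table_2x2 = tab,
      p_one_sided = p,
      degenerate_margin = degenerate
    ),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance_summary> %d animals, %d discordant under the recessive model\n",
              x$n_total, x$n_discordant))
  print(x$table_2x2)
  cat(sprintf("one-sided exact p = %.4g%s\n", x$p_one_sided,
              if (x$degenerate_margin) " (degenerate margin)" else ""))
  invisible(x)
}

#' @describeIn concordance The 2x2 table in long tibble form.
#' @param x A `concordance_summary`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.concordance_summary <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$table_2x2), stringsAsFactors = FALSE)) |>
    dplyr::rename(n = "Freq")
}

#' @describeIn concordance One-row summary with counts and the exact
#'   p-value.
#' @exportS3Method generics::glance
glance.concordance_summary <- function(x, ...) {
  tibble(
    n_total = x$n_total,
    n_affected_hom_alt = x$n_affected_hom_alt,
    n_unaffected_het = x$n_unaffected_het,
    n_unaffected_hom_ref = x$n_unaffected_hom_ref,
    n_discordant = x$n_discordant,
    p_one_sided = x$p_one_sided
  )
}

#' Plot a cohort concordance table
#'
#' Tile plot of the 2x2 genotype-by-phenotype table with counts printed in
#' each cell.
#'
#' @param object A `concordance_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.concordance_summary <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype, y = .data$genotype,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "black") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("Cohort concordance (n = %d, one-sided exact p = %.3g)",
                      object$n_total, object$p_one_sided),
      x = "phenotype", y = "genotype at candidate locus") +
    ggplot2::theme_minimal()
}
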