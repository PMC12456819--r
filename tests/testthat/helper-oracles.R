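# Independent oracles, written without the package's code paths, used to
# cross-check the vectorized implementations.

# Brute-force segregation matcher: plain per-variant, per-member loops.
oracle_filter <- function(variants, pedigree, required,
                          missing_policy = "strict") {
  surv <- character()
  for (i in seq_len(nrow(variants))) {
    ok <- TRUE
    n_considered <- 0L
    for (j in seq_len(nrow(pedigree))) {
      if (!pedigree$sequenced[j]) next
      aff <- pedigree$affection[j]
      if (aff == "unknown") next
      g <- variants[[pedigree$member_id[j]]][i]
      if (g == "missing") {
        if (missing_policy == "strict") {
          ok <- FALSE
          break
        }
        next
      }
      n_considered <- n_considered + 1L
      if (!(g %in% required[[aff]])) {
        ok <- FALSE
        break
      }
    }
    if (missing_policy == "ignore_sample" && ok && n_considered == 0L) {
      ok <- FALSE
    }
    if (ok) surv <- c(surv, variants$site_id[i])
  }
  surv
}

# Exhaustive hypergeometric-support enumeration with plain choose().
oracle_hyper_p <- function(x, K, N, n) {
  total <- choose(N, n)
  ways <- 0
  for (k in 0:min(K, n)) {
    if (n - k > N - K) next
    if (k >= x) ways <- ways + choose(K, k) * choose(N - K, n - k)
  }
  ways / total
}

# Codon translation through seqinr, independent of the implementation's
# genetic-code source.
oracle_translate <- function(codon) {
  toupper(seqinr::translate(tolower(strsplit(codon, "")[[1]])))
}

# Mendelian trio check: the offspring's allele pair must be formable from
# one allele of each parent.
oracle_trio_ok <- function(kid, father, mother) {
  pairs <- list(hom_ref = c(0, 0), het = c(0, 1), hom_alt = c(1, 1))
  for (a in pairs[[father]]) {
    for (b in pairs[[mother]]) {
      if (all(sort(c(a, b)) == sort(pairs[[kid]]))) return(TRUE)
    }
  }
  FALSE
}

# Three-member pedigree used for infeasibility and small-case tests.
trio_pedigree <- function(child_affection = "affected",
                          father_affection = "unaffected",
                          mother_affection = "unaffected") {
  as_pedigree(tibble::tibble(
    member_id = c("F", "M", "C"),
    father_id = c(NA, NA, "F"),
    mother_id = c(NA, NA, "M"),
    sex = c("male", "female", "male"),
    affection = c(father_affection, mother_affection, child_affection)
  ))
}

# Minimal hand-written VCF for reader tests.
write_test_vcf <- function(lines, samples = c("A", "B"),
                           path = withr::local_tempfile(fileext = ".vcf",
                                                        .local_envir = parent.frame())) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, lines), path)
  path
}
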