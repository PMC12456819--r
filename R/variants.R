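#' Classify a VCF GT string into a genotype class
#'
#' Reduces a per-sample GT value to one of the genotype classes the
#' segregation filter operates on. Phased (`|`) and unphased (`/`)
#' separators are treated identically; haploid calls are classified by their
#' single allele; any `.` allele makes the call `missing`. Alleles other
#' than the reference (0) and the focal alternate are classified `other`,
#' which is how multi-allelic genotypes such as `1/2` are represented after
#' per-alternate splitting.
#'
#' @param gt Character vector of GT values (`"0/1"`, `"1|1"`, `"./."`,
#'   `"1"`, ...).
#' @param alt_index Index (1-based within the ALT column) of the focal
#'   alternate allele; recycled along `gt`.
#' @return Character vector of classes: `hom_ref`, `het`, `hom_alt`,
#'   `missing` or `other`.
#' @examples
#' classify_genotype(c("0/1", "1|1", "./.", "1/2"))
#' @export
classify_genotype <- function(gt, alt_index = 1L) {
  gt <- as.character(gt)
  alt_index <- rep_len(as.integer(alt_index), length(gt))
  split <- strsplit(gt, "[/|]")
  vapply(seq_along(gt), function(i) {
    alleles <- split[[i]]
    focal <- alt_index[i]
    if (length(alleles) == 0 || any(!nzchar(alleles))) {
      abort("malformed GT value: empty allele")
    }
    if (any(alleles == ".")) return("missing")
    if (!all(grepl("^[0-9]+$", alleles))) {
      abort(sprintf("malformed GT value with non-numeric allele: '%s'",
                    paste(alleles, collapse = "/")))
    }
    idx <- as.integer(alleles)
    if (any(idx != 0L & idx != focal)) return("other")
    n_alt <- sum(idx == focal)
    if (length(idx) == 1L) {
      if (n_alt == 1L) "hom_alt" else "hom_ref"
    } else if (n_alt == length(idx)) {
      "hom_alt"
    } else if (n_alt == 0L) {
      "hom_ref"
    } else {
      "het"
    }
  }, character(1))
}

#' Parse a SnpEff/VEP-style ANN INFO field
#'
#' Extracts functional annotation entries from a VCF INFO string in the
#' pipe-delimited `ANN` dialect
#' (`Allele|Annotation|Impact|Gene_Name|Gene_ID|Feature_Type|Feature_ID|`
#' `Biotype|Rank|HGVS.c|HGVS.p|...`), with multiple entries separated by
#' commas and multiple effect terms within an entry joined by `&`.
#' Entries with fewer than two pipe fields are skipped with a warning
#' (tolerant parse).
#'
#' @param info A single INFO string (the whole INFO column value or just the
#'   `ANN=...` part).
#' @return A tibble with one row per annotation entry and columns `allele`,
#'   `effect` (list-column of effect-term character vectors), `impact`,
#'   `gene`, `transcript`, `hgvs_c`, `hgvs_p`. Zero rows when no ANN field
#'   is present.
#' @examples
#' parse_ann("ANN=T|missense_variant|MODERATE|Pde6b|ENSMUSG00000029491|transcript|tx1|protein_coding|13/22|c.1678C>T|p.Arg560Cys")
#' @export
parse_ann <- function(info) {
  new_ann <- function(cols, n) {
    tibble::new_tibble(cols, nrow = n)
  }
  empty <- new_ann(list(allele = character(), effect = list(),
                        impact = character(), gene = character(),
                        transcript = character(), hgvs_c = character(),
                        hgvs_p = character()), 0L)
  if (length(info) != 1 || is.na(info) || !nzchar(info)) return(empty)
  fields <- strsplit(info, ";", fixed = TRUE)[[1]]
  ann <- fields[startsWith(fields, "ANN=")]
  if (length(ann) == 0) {
    # tolerate being handed the bare ANN value (contains pipes, no '=')
    if (grepl("|", info, fixed = TRUE) && !grepl("=", info, fixed = TRUE)) {
      ann <- paste0("ANN=", info)
    } else {
      return(empty)
    }
  }
  entries <- strsplit(sub("^ANN=", "", ann[[1]]), ",", fixed = TRUE)[[1]]
  fs <- strsplit(entries, "|", fixed = TRUE)
  keep <- lengths(fs) >= 2
  for (e in entries[!keep]) {
    warn(sprintf("skipping malformed ANN entry '%s'", e))
  }
  fs <- fs[keep]
  if (length(fs) == 0) return(empty)
  field <- function(i) {
    vapply(fs, function(f)
      if (length(f) >= i && nzchar(f[i])) f[i] else NA_character_,
      character(1))
  }
  new_ann(list(
    allele = field(1),
    effect = lapply(fs, function(f) strsplit(f[2], "&", fixed = TRUE)[[1]]),
    impact = field(3),
    gene = field(4),
    transcript = field(7),
    hgvs_c = field(10),
    hgvs_p = field(11)
  ), length(fs))
}

new_variant_tbl <- function(df, samples) {
  df <- as_tibble(df)
  attr(df, "samples") <- samples
  class(df) <- unique(c("variant_tbl", class(df)))
  df
}

#' Sample ids carried by a variant table
#'
#' @param variants A variant tibble from [read_vcf()] or
#'   [simulate_cosegregation()].
#' @return Character vector of sample ids (the per-sample genotype-class
#'   columns of the table).
#' @export
vcf_samples <- function(variants) {
  s <- attr(variants, "samples")
  if (is.null(s)) {
    abort("not a variant table: missing 'samples' attribute")
  }
  s
}

#' Read a multi-sample VCF into a variant table
#'
#' Reads a VCF (v4.2, plain or bgzipped) and classifies every per-sample GT
#' call into a genotype class. Multi-allelic lines are split into one row
#' per alternate allele, with genotypes re-expressed relative to the focal
#' alternate (other non-reference alleles become class `other`). `ANN`
#' annotations, when present, are parsed into a list-column; after a
#' multi-allelic split only the entries whose allele matches the focal
#' alternate are kept (all entries are kept if none matches).
#'
#' @param path Path to a VCF file.
#' @param samples Optional character vector restricting the genotype columns
#'   to a subset of the header samples (error if any is absent).
#' @param min_qual Optional minimum QUAL; sites below it (or with missing
#'   QUAL) are dropped. Off by default: no site-quality filtering beyond the
#'   upstream caller's own is applied.
#' @param require_pass If `TRUE`, keep only sites whose FILTER is `PASS` or
#'   `.`. Off by default.
#' @return A `variant_tbl` tibble, one row per (site, alternate allele), in
#'   file order, with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `filter`, `site_id` (`chrom:pos:ref>alt`), `ann` (list-column of
#'   annotation tibbles) and one genotype-class column per sample.
#' @export
read_vcf <- function(path, samples = NULL, min_qual = NULL,
                     require_pass = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  header_samples <- colnames(vcf@gt)
  if (is.null(header_samples) || length(header_samples) < 2 ||
      header_samples[1] != "FORMAT") {
    abort("VCF has no FORMAT/genotype columns; per-sample GT calls are required")
  }
  header_samples <- header_samples[-1]
  if (is.null(samples)) samples <- header_samples
  absent <- setdiff(samples, header_samples)
  if (length(absent) > 0) {
    abort(paste0("sample(s) requested but absent from VCF header: ",
                 paste(absent, collapse = ", ")))
  }

  fix <- vcf@fix
  n <- nrow(fix)
  if (n == 0) {
    cols <- c(list(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), qual = double(), filter = character(),
                   site_id = character(), ann = list()),
              setNames(rep(list(character()), length(samples)), samples))
    return(new_variant_tbl(tibble::as_tibble(cols), samples))
  }
  if (!all(grepl("GT", vcf@gt[, "FORMAT"]))) {
    abort("one or more VCF records lack the GT FORMAT field")
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = n,
                                             dimnames = list(NULL, header_samples))
  gt_raw <- gt_raw[, samples, drop = FALSE]
  gt_raw[is.na(gt_raw)] <- "."

  # expand multi-allelic lines: one output row per (line, alternate allele)
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  line <- rep.int(seq_len(n), n_alt)
  alt_k <- sequence(n_alt)
  alt <- unname(unlist(alt_list))

  has_ann <- grepl("ANN=", fix[, "INFO"], fixed = TRUE)
  no_ann <- parse_ann(NA_character_)
  ann <- lapply(seq_along(line), function(j) {
    i <- line[j]
    if (!has_ann[i]) return(no_ann)
    a <- parse_ann(fix[i, "INFO"])
    if (nrow(a) > 0 && n_alt[i] > 1 &&
        any(!is.na(a$allele) & a$allele == alt[j])) {
      a <- a[!is.na(a$allele) & a$allele == alt[j], ]
    }
    a
  })

  out <- tibble(
    chrom = fix[line, "CHROM"],
    pos = as.integer(fix[line, "POS"]),
    ref = fix[line, "REF"],
    alt = alt,
    qual = suppressWarnings(as.numeric(fix[line, "QUAL"])),
    filter = fix[line, "FILTER"],
    ann = ann
  )
  out$site_id <- paste0(out$chrom, ":", out$pos, ":", out$ref, ">", out$alt)
  for (s in samples) {
    out[[s]] <- tryCatch(
      classify_genotype(gt_raw[line, s], alt_index = alt_k),
      error = function(e) {
        abort(sprintf("sample %s: %s", s, conditionMessage(e)))
      })
  }
  out <- out[, c("chrom", "pos", "ref", "alt", "qual", "filter", "site_id",
                 "ann", samples)]
  if (!is.null(min_qual)) {
    out <- out[!is.na(out$qual) & out$qual >= min_qual, ]
  }
  if (require_pass) {
    out <- out[is.na(out$filter) | out$filter %in% c("PASS", "."), ]
  }
  new_variant_tbl(out, samples)
}

class_to_gt <- function(classes) {
  bad <- setdiff(unique(classes), c("hom_ref", "het", "hom_alt", "missing"))
  if (length(bad) > 0) {
    abort(paste0("cannot serialize genotype class(es) to a biallelic GT: ",
                 paste(bad, collapse = ", ")))
  }
  dplyr::case_match(classes, "hom_ref" ~ "0/0", "het" ~ "0/1",
                    "hom_alt" ~ "1/1", "missing" ~ "./.")
}

serialize_ann <- function(ann, alt) {
  if (is.null(ann) || nrow(ann) == 0) return(NA_character_)
  entries <- vapply(seq_len(nrow(ann)), function(i) {
    f <- rep("", 11)
    f[1] <- ann$allele[i]
    if (is.na(f[1])) f[1] <- alt
    f[2] <- paste(ann$effect[[i]], collapse = "&")
    f[3] <- ifelse(is.na(ann$impact[i]), "", ann$impact[i])
    f[4] <- ifelse(is.na(ann$gene[i]), "", ann$gene[i])
    f[5] <- f[4]
    f[6] <- "transcript"
    f[7] <- ifelse(is.na(ann$transcript[i]), "", ann$transcript[i])
    f[10] <- ifelse(is.na(ann$hgvs_c[i]), "", ann$hgvs_c[i])
    f[11] <- ifelse(is.na(ann$hgvs_p[i]), "", ann$hgvs_p[i])
    paste(f, collapse = "|")
  }, character(1))
  paste0("ANN=", paste(entries, collapse = ","))
}

#' Write a variant table to a VCF file
#'
#' Serializes a variant table back to plain-text VCF v4.2 with one GT-only
#' genotype column per sample, in the stored sample order. Only biallelic
#' genotype classes (`hom_ref`, `het`, `hom_alt`, `missing`) can be
#' serialized; class `other` has no biallelic GT representation and raises
#' an error. The output contains no timestamps, so identical inputs produce
#' byte-identical files.
#'
#' @param variants A `variant_tbl` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  samples <- vcf_samples(variants)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cosegr",
    paste0("##contig=<ID=", paste(unique(variants$chrom), collapse = ">\n##contig=<ID="), ">"),
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID | Feature_Type | Feature_ID | Transcript_BioType | Rank | HGVS.c | HGVS.p'\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  if (nrow(variants) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  info <- vapply(seq_len(nrow(variants)),
                 function(i) serialize_ann(variants$ann[[i]],
                                           variants$alt[i]),
                 character(1))
  info[is.na(info)] <- "."
  gt_cols <- vapply(samples, function(s) class_to_gt(variants[[s]]),
                    character(nrow(variants)))
  if (is.null(dim(gt_cols))) gt_cols <- matrix(gt_cols, nrow = 1,
                                               dimnames = list(NULL, samples))
  body <- paste(
    variants$chrom, variants$pos, ".", variants$ref, variants$alt,
    ifelse(is.na(variants$qual), ".", format(variants$qual, trim = TRUE)),
    ifelse(is.na(variants$filter), ".", variants$filter),
    info, "GT",
    apply(gt_cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
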