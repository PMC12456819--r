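#' Run the full cosegregation filtering workflow
#'
#' Reads a multi-sample VCF and a PED pedigree, evaluates every requested
#' inheritance model in one pass over the variants, triages survivors by
#' consequence class and assembles the machine-readable run report: input
#' digests, per-model filtering summaries, and a candidate table of
#' protein-coding survivors with their gene, HGVS descriptions and an
#' internal consistency check (does the coding position's codon index match
#' the protein position printed in the `p.` description?). Models are
#' reported in sorted order, so the report does not depend on the order
#' they were requested in. An empty candidate list is a result, not an
#' error.
#'
#' @param vcf Path to the VCF.
#' @param ped Path to the PED pedigree.
#' @param models Character vector of inheritance-model ids (or a list of
#'   `inheritance_model` objects).
#' @param missing_policy `"strict"` or `"ignore_sample"`.
#' @param max_discordant Discordant members tolerated (default 0).
#' @param min_qual,require_pass Passed to [read_vcf()].
#' @param coding_terms Effect terms counted as protein-coding.
#' @param out_dir Optional directory; when given, writes `report.json` and
#'   one `survivors_<model>.tsv` per model.
#' @return A `run_report` list with elements `inputs`, `pedigree`,
#'   `results` (named list of `segregation_result`), `summary` (one row
#'   per model), `candidates` (tibble of protein-coding survivors) and
#'   `config`.
#' @export
run_filter <- function(vcf, ped, models = c("het_carrier_hom_affected",
                                            "wt_carrier_het_affected"),
                       missing_policy = c("strict", "ignore_sample"),
                       max_discordant = 0L, min_qual = NULL,
                       require_pass = FALSE,
                       coding_terms = protein_coding_terms,
                       out_dir = NULL) {
  missing_policy <- match.arg(missing_policy)
  pedigree <- read_ped(ped)
  variants <- read_vcf(vcf, min_qual = min_qual,
                       require_pass = require_pass)
  seq_members <- pedigree$member_id[pedigree$sequenced]
  absent <- setdiff(seq_members, vcf_samples(variants))
  if (length(absent) > 0) {
    abort(paste0(
      "sample-name mismatch between VCF and PED; sequenced member(s) not in VCF: ",
      paste(absent, collapse = ", ")))
  }

  models <- lapply(models, as_inheritance_model)
  ids <- vapply(models, function(m) m$model_id, character(1))
  models <- models[order(ids)]
  ids <- sort(ids)

  results <- lapply(models, function(m)
    segregate(variants, pedigree, m, missing_policy = missing_policy,
              max_discordant = max_discordant,
              coding_terms = coding_terms))
  names(results) <- ids

  summary <- dplyr::bind_rows(lapply(results, glance))
  candidates <- dplyr::bind_rows(lapply(results, candidate_table))

  report <- structure(
    list(
      inputs = list(
        vcf = list(path = vcf, md5 = unname(tools::md5sum(vcf)),
                   samples = vcf_samples(variants),
                   n_variants = nrow(variants)),
        ped = list(path = ped, md5 = unname(tools::md5sum(ped)),
                   members = pedigree$member_id)
      ),
      pedigree = pedigree,
      results = results,
      summary = summary,
      candidates = candidates,
      config = list(models = ids, missing_policy = missing_policy,
                    max_discordant = max_discordant,
                    min_qual = min_qual, require_pass = require_pass,
                    coding_terms = coding_terms,
                    version = as.character(utils::packageVersion("cosegr")))
    ),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Candidate table of protein-coding survivors
#'
#' @param result A `segregation_result`.
#' @return Tibble with one row per protein-coding surviving variant:
#'   `model_id`, `site_id`, `gene`, `hgvs_c`, `hgvs_p` and
#'   `consistency_check` (`TRUE`/`FALSE`/`NA`).
#' @export
candidate_table <- function(result) {
  surv <- tidy(result)
  surv <- surv[surv$consequence == "protein_coding", , drop = FALSE]
  if (nrow(surv) == 0) {
    return(tibble(model_id = character(), site_id = character(),
                  gene = character(), hgvs_c = character(),
                  hgvs_p = character(), consistency_check = logical()))
  }
  hgvs_c <- vapply(surv$ann, function(a)
    if (nrow(a) == 0) NA_character_ else a$hgvs_c[1], character(1))
  hgvs_p <- vapply(surv$ann, function(a)
    if (nrow(a) == 0) NA_character_ else a$hgvs_p[1], character(1))
  consistency <- mapply(function(cc, pp) {
    if (is.na(cc) || is.na(pp)) return(NA)
    parsed <- tryCatch(parse_hgvs_c(cc), error = function(e) NULL)
    ppos <- hgvs_p_position(pp)
    if (is.null(parsed) || is.na(ppos)) return(NA)
    parsed$codon_index == ppos
  }, hgvs_c, hgvs_p, USE.NAMES = FALSE)
  tibble(model_id = surv$model_id, site_id = surv$site_id,
         gene = surv$gene, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
         consistency_check = as.logical(consistency))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  VCF: %s (%d variants, %d samples)\n", x$inputs$vcf$path,
              x$inputs$vcf$n_variants, length(x$inputs$vcf$samples)))
  print(x$summary)
  cat(sprintf("  %d protein-coding candidate(s)\n", nrow(x$candidates)))
  invisible(x)
}

# JSON + TSV serialization of a run report; content is fully derived from
# inputs and config (no timestamps), so reruns are byte-identical.
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(report$results)) {
    res <- report$results[[id]]
    surv <- tidy(res)
    samples <- report$inputs$vcf$samples
    tsv <- dplyr::select(surv, "model_id", "site_id", "consequence",
                         "gene", dplyr::all_of(samples))
    utils::write.table(tsv,
                       file.path(out_dir, paste0("survivors_", id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  # input paths are recorded by basename so that identical inputs produce
  # identical reports wherever they live; the md5 pins the content
  inputs <- report$inputs
  inputs$vcf$path <- basename(inputs$vcf$path)
  inputs$ped$path <- basename(inputs$ped$path)
  json <- list(
    inputs = inputs,
    config = report$config,
    models = lapply(report$results, function(res) list(
      model_id = res$model_id,
      n_input = res$n_input,
      n_surviving = res$n_surviving,
      per_class_counts = as.list(res$per_class_counts),
      exclusions = as.list(res$exclusions)
    )),
    candidates = report$candidates
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' Run the simulator and write its outputs
#'
#' Thin wrapper over [simulate_cosegregation()] and [write_simulation()]
#' that logs the seed and a digest of the written files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param prefix File-name prefix.
#' @return Named vector of written paths, invisibly.
#' @export
run_simulate <- function(config, out_dir, prefix = "sim") {
  sim <- simulate_cosegregation(config)
  paths <- write_simulation(sim, out_dir, prefix)
  inform(sprintf("seed %d -> %s (md5 %s)", config$seed,
                 paste(basename(paths), collapse = ", "),
                 paste(substr(tools::md5sum(paths), 1, 8), collapse = ", ")))
  invisible(paths)
}

#' Run the cohort concordance check from a table on disk
#'
#' @param table_path Path to a cohort TSV/CSV (see [read_cohort()]).
#' @return A `concordance_summary`.
#' @export
run_cohort <- function(table_path) {
  concordance(read_cohort(table_path))
}
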