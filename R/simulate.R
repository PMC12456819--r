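#' The packaged study family pedigree
#'
#' The ten-member nuclear family used throughout the examples and as the
#' simulator's default pedigree: an affected father (294), an unaffected
#' mother (367), four affected sons (408, 409, 410, 411), one affected
#' daughter (381), two unaffected sons (407, 412) and one unaffected
#' daughter (382). All members are flagged sequenced by default; pass ids
#' via `unsequenced` to emulate designs where some family members were not
#' sequenced.
#'
#' The same family ships as a PED fixture at
#' `system.file("extdata", "rd6_family.ped", package = "cosegr")`.
#'
#' @param unsequenced Character vector of member ids to flag as not
#'   sequenced.
#' @return A `pedigree` tibble of 2 founders and 8 offspring.
#' @export
rd6_family <- function(unsequenced = character()) {
  kids_aff <- c("408", "409", "410", "411", "381")
  members <- tibble(
    family_id = "RD6",
    member_id = c("294", "367", "407", "408", "409", "410", "411", "412",
                  "381", "382"),
    father_id = c(NA, NA, rep("294", 8)),
    mother_id = c(NA, NA, rep("367", 8)),
    sex = c("male", "female", "male", "male", "male", "male", "male",
            "male", "female", "female"),
    affection = c("affected", "unaffected",
                  ifelse(c("407", "408", "409", "410", "411", "412",
                           "381", "382") %in% kids_aff,
                         "affected", "unaffected")),
    sequenced = TRUE
  )
  ped <- as_pedigree(members)
  if (length(unsequenced) > 0) {
    ped$sequenced[ped$member_id %in% unsequenced] <- FALSE
  }
  ped
}

#' Founder allele-frequency laws
#'
#' `af_beta()` draws each background variant's founder alternate-allele
#' frequency from a Beta distribution; the default Beta(0.5, 0.5) produces
#' both common and rare variants, mimicking a site-frequency spectrum with
#' mass near the boundaries. `af_fixed()` pins the frequency, which makes
#' closed-form survival expectations exact and is used for calibration.
#'
#' @param alpha,beta Beta shape parameters.
#' @param q Fixed allele frequency in (0, 1).
#' @return A founder allele-frequency law object.
#' @name founder_af_law
NULL

#' @rdname founder_af_law
#' @export
af_beta <- function(alpha = 0.5, beta = 0.5) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(law = "beta", alpha = alpha, beta = beta),
            class = "founder_af_law")
}

#' @rdname founder_af_law
#' @export
af_fixed <- function(q) {
  stopifnot(q > 0, q < 1)
  structure(list(law = "fixed", q = q), class = "founder_af_law")
}

draw_af <- function(law, n) {
  if (law$law == "fixed") {
    rep(law$q, n)
  } else {
    # clamp away from 0/1 so HWE classes and closed forms stay defined
    pmin(pmax(stats::rbeta(n, law$alpha, law$beta), 1e-6), 1 - 1e-6)
  }
}

#' Causal-variant specification for the simulator
#'
#' Describes the variant planted into a simulated dataset: the inheritance
#' model its genotypes follow (deterministically assigned from each
#' member's affection status) and the annotation template attached to it.
#' The default template reproduces the annotation shape of a known
#' recessive retinal-degeneration allele: a missense change in *Pde6b*,
#' c.1678C>T (p.Arg560Cys), the rd10 allele.
#'
#' @param model Built-in inheritance model id the planted genotypes follow.
#' @param gene,effect,impact,hgvs_c,hgvs_p Annotation fields written to the
#'   causal record's ANN entry.
#' @return A `causal_spec` list.
#' @export
causal_spec <- function(model = "het_carrier_hom_affected",
                        gene = "Pde6b", effect = "missense_variant",
                        impact = "MODERATE", hgvs_c = "c.1678C>T",
                        hgvs_p = "p.Arg560Cys") {
  structure(list(model = model, gene = gene, effect = effect,
                 impact = impact, hgvs_c = hgvs_c, hgvs_p = hgvs_p),
            class = "causal_spec")
}

#' Configure a gene-dropping simulation
#'
#' Bundles everything that determines a simulated dataset. In `pedigree`
#' mode, founder genotypes are drawn under Hardy–Weinberg proportions at a
#' per-variant allele frequency from `founder_af`, and each offspring
#' receives one uniformly random allele from each parent (gene dropping;
#' variants are independent, with no linkage). In `unrelated_panel` mode
#' every individual is drawn independently under Hardy–Weinberg — the
#' configuration under which the closed-form null survival expectation of
#' [expected_null_survival()] holds exactly.
#'
#' Genotyping error (a call re-drawn to a uniformly random wrong
#' informative class) and missingness are applied after the clean truth is
#' recorded. The causal variant never receives error or missingness unless
#' `corrupt_causal = TRUE`, so recovery tests have a clean needle by
#' default and a stress mode on demand.
#'
#' @param pedigree A `pedigree` tibble (sex required for all members);
#'   defaults to [rd6_family()].
#' @param n_background Number of neutral background variants.
#' @param founder_af Founder allele-frequency law ([af_beta()] or
#'   [af_fixed()]).
#' @param genotyping_error_rate Per-call probability in \[0, 1) of
#'   replacing a call with a uniformly random wrong informative class.
#' @param missing_rate Per-call probability in \[0, 1) of masking a call to
#'   `missing`.
#' @param causal A [causal_spec()], or `NULL` for no planted variant.
#' @param mode `"pedigree"` or `"unrelated_panel"`.
#' @param corrupt_causal If `TRUE`, error and missingness also hit the
#'   causal record.
#' @param ann_proportions Named proportions (`protein_coding`, `intronic`,
#'   `intergenic`) from which background annotation classes are drawn.
#' @param seed Integer seed; the seed fully determines the output,
#'   byte-for-byte.
#' @return A `sim_config` list.
#' @export
sim_config <- function(pedigree = rd6_family(), n_background = 10000L,
                       founder_af = af_beta(0.5, 0.5),
                       genotyping_error_rate = 0, missing_rate = 0,
                       causal = causal_spec(), mode = c("pedigree",
                                                        "unrelated_panel"),
                       corrupt_causal = FALSE,
                       ann_proportions = c(protein_coding = 0.01,
                                           intronic = 0.33,
                                           intergenic = 0.66),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (!inherits(founder_af, "founder_af_law")) {
    abort("`founder_af` must be built with af_beta() or af_fixed()")
  }
  if (genotyping_error_rate < 0 || genotyping_error_rate >= 1) {
    abort("`genotyping_error_rate` must be in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1)")
  }
  if (n_background < 0) abort("`n_background` must be >= 0")
  if (!is.null(causal) && !inherits(causal, "causal_spec")) {
    abort("`causal` must be NULL or built with causal_spec()")
  }
  if (any(pedigree$sex == "unknown")) {
    abort("simulation requires known sex for every pedigree member")
  }
  stopifnot(setequal(names(ann_proportions),
                     c("protein_coding", "intronic", "intergenic")),
            all(ann_proportions >= 0), sum(ann_proportions) > 0)
  structure(
    list(pedigree = pedigree, n_background = as.integer(n_background),
         founder_af = founder_af,
         genotyping_error_rate = genotyping_error_rate,
         missing_rate = missing_rate, causal = causal, mode = mode,
         corrupt_causal = corrupt_causal,
         ann_proportions = ann_proportions, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Gene dropping: founders drawn under HWE at the per-variant frequency,
# offspring inherit one uniformly random allele from each parent. Returns a
# 0/1/2 alternate-allele dosage matrix (variants x members). In
# unrelated_panel mode every member is drawn as a founder.
drop_dosages <- function(pedigree, q, mode) {
  n <- length(q)
  ord <- order(pedigree$generation, seq_len(nrow(pedigree)))
  alleles <- list()
  for (i in ord) {
    id <- pedigree$member_id[i]
    if (mode == "unrelated_panel" || is.na(pedigree$father_id[i])) {
      alleles[[id]] <- cbind(stats::rbinom(n, 1L, q),
                             stats::rbinom(n, 1L, q))
    } else {
      pa <- alleles[[pedigree$father_id[i]]]
      ma <- alleles[[pedigree$mother_id[i]]]
      from_f <- ifelse(stats::runif(n) < 0.5, pa[, 1], pa[, 2])
      from_m <- ifelse(stats::runif(n) < 0.5, ma[, 1], ma[, 2])
      alleles[[id]] <- cbind(from_f, from_m)
    }
  }
  dosage <- matrix(0L, n, nrow(pedigree),
                   dimnames = list(NULL, pedigree$member_id))
  for (id in pedigree$member_id) {
    dosage[, id] <- alleles[[id]][, 1] + alleles[[id]][, 2]
  }
  dosage
}

dosage_to_class <- function(dosage) {
  matrix(c("hom_ref", "het", "hom_alt")[dosage + 1L],
         nrow = nrow(dosage), ncol = ncol(dosage),
         dimnames = dimnames(dosage))
}

# Deterministic causal genotypes from affection under a built-in model,
# with a trio-wise Mendelian feasibility check.
causal_classes <- function(pedigree, model) {
  model <- as_inheritance_model(model)
  if (any(pedigree$affection == "unknown")) {
    abort("planting a causal variant requires known affection for every pedigree member")
  }
  req <- model$required[pedigree$affection]
  if (any(lengths(req) != 1)) {
    abort("causal planting requires a model mapping each affection state to exactly one genotype class")
  }
  cls <- setNames(unlist(req), pedigree$member_id)
  allele_sets <- list(hom_ref = c(0L, 0L), het = c(0L, 1L),
                      hom_alt = c(1L, 1L))
  for (i in which(!is.na(pedigree$father_id))) {
    kid <- allele_sets[[cls[pedigree$member_id[i]]]]
    fa <- allele_sets[[cls[pedigree$father_id[i]]]]
    mo <- allele_sets[[cls[pedigree$mother_id[i]]]]
    # the offspring pair must be formable from one allele of each parent
    ok <- FALSE
    for (a in unique(fa)) for (b in unique(mo)) {
      if (all(sort(c(a, b)) == sort(kid))) ok <- TRUE
    }
    if (!ok) {
      abort(sprintf(
        "affection pattern is impossible under model '%s': offspring %s (%s) cannot arise from father %s (%s) and mother %s (%s)",
        model$model_id,
        pedigree$member_id[i], cls[pedigree$member_id[i]],
        pedigree$father_id[i], cls[pedigree$father_id[i]],
        pedigree$mother_id[i], cls[pedigree$mother_id[i]]))
    }
  }
  cls
}

apply_error_missing <- function(cls, error_rate, missing_rate, skip_rows) {
  n <- nrow(cls)
  if (n == 0) return(cls)
  m <- ncol(cls)
  editable <- matrix(TRUE, n, m)
  if (length(skip_rows) > 0) editable[skip_rows, ] <- FALSE
  if (error_rate > 0) {
    hit <- matrix(stats::runif(n * m) < error_rate, n, m) & editable &
      cls %in% GT_INFORMATIVE
    if (any(hit)) {
      others <- list(hom_ref = c("het", "hom_alt"),
                     het = c("hom_ref", "hom_alt"),
                     hom_alt = c("hom_ref", "het"))
      pick <- stats::runif(sum(hit)) < 0.5
      idx <- which(hit)
      cur <- cls[idx]
      cls[idx] <- vapply(seq_along(idx), function(k)
        others[[cur[k]]][if (pick[k]) 1L else 2L], character(1))
    }
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < missing_rate, n, m) & editable
    cls[miss] <- "missing"
  }
  cls
}

#' Attach annotations to a simulated variant table
#'
#' Writes the causal record's ANN entry from its annotation template and
#' draws a consequence class for every background record from the
#' configured proportions (`protein_coding` records get a missense entry,
#' `intronic` an intron entry, `intergenic` an intergenic entry). Uses the
#' current RNG state; [simulate_cosegregation()] calls this after seeding
#' so the result is reproducible.
#'
#' @param variants A `variant_tbl`.
#' @param causal_site_id Site id of the causal record, or `NA`.
#' @param causal A [causal_spec()] (ignored when `causal_site_id` is `NA`).
#' @param proportions Named proportions over `protein_coding`, `intronic`,
#'   `intergenic` for the background records.
#' @return The variant table with its `ann` list-column populated.
#' @export
plant_annotations <- function(variants, causal_site_id, causal,
                              proportions = c(protein_coding = 0.01,
                                              intronic = 0.33,
                                              intergenic = 0.66)) {
  n <- nrow(variants)
  if (n == 0) return(variants)
  classes <- sample(names(proportions), n, replace = TRUE,
                    prob = proportions)
  # one template per class, cloned per record: building n fresh tibbles is
  # needlessly slow at simulation scale
  templates <- list(
    protein_coding = tibble(
      allele = NA_character_, effect = list("missense_variant"),
      impact = "MODERATE", gene = NA_character_,
      transcript = NA_character_, hgvs_c = NA_character_,
      hgvs_p = NA_character_),
    intronic = tibble(
      allele = NA_character_, effect = list("intron_variant"),
      impact = "MODIFIER", gene = NA_character_,
      transcript = NA_character_, hgvs_c = NA_character_,
      hgvs_p = NA_character_),
    intergenic = tibble(
      allele = NA_character_, effect = list("intergenic_region"),
      impact = "MODIFIER", gene = NA_character_,
      transcript = NA_character_, hgvs_c = NA_character_,
      hgvs_p = NA_character_)
  )
  genes <- sprintf("Gene%05d", seq_len(n))
  alts <- variants$alt
  ann <- lapply(seq_len(n), function(i) {
    a <- templates[[classes[i]]]
    a[["allele"]] <- alts[i]
    if (classes[i] != "intergenic") a[["gene"]] <- genes[i]
    a
  })
  if (!is.na(causal_site_id)) {
    i <- which(variants$site_id == causal_site_id)
    ann[[i]] <- tibble(
      allele = variants$alt[i], effect = list(causal$effect),
      impact = causal$impact, gene = causal$gene,
      transcript = NA_character_, hgvs_c = causal$hgvs_c,
      hgvs_p = causal$hgvs_p)
  }
  variants$ann <- ann
  variants
}

#' Simulate a family dataset by gene dropping
#'
#' Generates a pedigree-consistent multi-sample genotype dataset with an
#' optional planted causal variant, as configured by [sim_config()].
#' Background variants sit every 100 bp along a single synthetic contig
#' (`chrSim`); coordinates carry no meaning in the filter. The clean truth
#' (pre-error, pre-missingness genotype classes and per-variant founder
#' allele frequencies) is recorded before corruption is applied.
#'
#' @param config A [sim_config()].
#' @return A `cosegregation_sim` object: list with `pedigree`, `variants`
#'   (a `variant_tbl` ready for [segregate()] or [write_vcf()]), `truth`
#'   (list with `classes` — the clean class matrix —, `causal_site_id`,
#'   `allele_freq`) and `config`.
#' @examples
#' sim <- simulate_cosegregation(sim_config(n_background = 100, seed = 7))
#' res <- segregate(sim$variants, sim$pedigree, "het_carrier_hom_affected")
#' sim$truth$causal_site_id %in% tidy(res)$site_id
#' @export
simulate_cosegregation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ped <- config$pedigree
  members <- ped$member_id
  n_bg <- config$n_background

  q <- draw_af(config$founder_af, n_bg)
  cls <- dosage_to_class(drop_dosages(ped, q, config$mode))

  causal_row <- NA_integer_
  if (!is.null(config$causal)) {
    ccls <- causal_classes(ped, config$causal$model)
    causal_row <- if (n_bg > 0) sample.int(n_bg + 1L, 1L) else 1L
    cls <- rbind(cls[seq_len(causal_row - 1L), , drop = FALSE],
                 matrix(ccls[members], nrow = 1,
                        dimnames = list(NULL, members)),
                 cls[seq(causal_row, length.out = n_bg - causal_row + 1L), ,
                     drop = FALSE])
    q <- append(q, NA_real_, after = causal_row - 1L)
  }
  n <- nrow(cls)

  pos <- seq_len(n) * 100L
  bases <- c("A", "C", "G", "T")
  ref_idx <- if (n > 0) sample.int(4L, n, replace = TRUE) else integer()
  ref <- bases[ref_idx]
  # alternate drawn uniformly from the other three bases
  alt <- bases[(ref_idx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
  if (!is.na(causal_row) && !is.null(config$causal$hgvs_c)) {
    parsed <- tryCatch(parse_hgvs_c(config$causal$hgvs_c),
                       error = function(e) NULL)
    if (!is.null(parsed)) {
      ref[causal_row] <- parsed$ref_base
      alt[causal_row] <- parsed$alt_base
    }
  }

  truth_classes <- cls
  corrupted <- apply_error_missing(
    cls, config$genotyping_error_rate, config$missing_rate,
    skip_rows = if (!is.na(causal_row) && !config$corrupt_causal)
      causal_row else integer())

  site_id <- if (n > 0) paste0("chrSim:", pos, ":", ref, ">", alt)
             else character()
  base <- tibble(chrom = rep("chrSim", n), pos = pos, ref = ref, alt = alt,
                 qual = rep(NA_real_, n), filter = rep("PASS", n),
                 site_id = site_id,
                 ann = rep(list(parse_ann(NA_character_)), n))
  for (s in members) base[[s]] <- unname(corrupted[, s])
  variants <- new_variant_tbl(base, members)

  causal_site_id <- if (is.na(causal_row)) NA_character_
                    else site_id[causal_row]
  variants <- plant_annotations(variants, causal_site_id, config$causal,
                                config$ann_proportions)

  if (n > 0) rownames(truth_classes) <- site_id
  structure(
    list(pedigree = ped, variants = variants,
         truth = list(classes = truth_classes,
                      causal_site_id = causal_site_id,
                      allele_freq = setNames(as.numeric(q), site_id)),
         config = config),
    class = "cosegregation_sim"
  )
}

#' @export
print.cosegregation_sim <- function(x, ...) {
  cat(sprintf("<cosegregation_sim> %d variants x %d members (%s mode, seed %d)\n",
              nrow(x$variants), nrow(x$pedigree), x$config$mode,
              x$config$seed))
  if (!is.na(x$truth$causal_site_id)) {
    cat(sprintf("  causal variant planted at %s\n", x$truth$causal_site_id))
  }
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the PED, the VCF and a JSON truth sidecar (causal site, seed,
#' per-variant founder allele frequency and the clean genotype classes).
#' Outputs contain no timestamps: the same configuration and seed produce
#' byte-identical files.
#'
#' @param sim A `cosegregation_sim`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ped = file.path(dir, paste0(prefix, ".ped")),
             vcf = file.path(dir, paste0(prefix, ".vcf")),
             truth = file.path(dir, paste0(prefix, ".truth.json")))
  write_ped(sim$pedigree, paths["ped"])
  write_vcf(sim$variants, paths["vcf"])
  truth <- list(
    seed = sim$config$seed,
    mode = sim$config$mode,
    n_variants = nrow(sim$variants),
    causal_site_id = sim$truth$causal_site_id,
    allele_freq = unname(sim$truth$allele_freq),
    site_id = rownames(sim$truth$classes),
    classes = as.data.frame(sim$truth$classes)
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = FALSE)
  invisible(paths)
}
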