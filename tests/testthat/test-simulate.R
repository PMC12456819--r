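test_that("a causal-only simulation carries the exact model-1 genotypes", {
  sim <- simulate_cosegregation(sim_config(n_background = 0, seed = 1))
  expect_equal(nrow(sim$variants), 1)
  affected <- c("294", "408", "409", "410", "411", "381")
  for (m in affected) expect_equal(sim$variants[[m]], "hom_alt")
  for (m in c("367", "407", "412", "382")) {
    expect_equal(sim$variants[[m]], "het")
  }
  # the template's coding change fixes the causal ref/alt bases
  expect_equal(sim$variants$ref, "C")
  expect_equal(sim$variants$alt, "T")
  expect_equal(sim$truth$causal_site_id, sim$variants$site_id)
})

test_that("a model-2 causal variant assigns het to affected, hom_ref to unaffected", {
  sim <- simulate_cosegregation(sim_config(
    n_background = 0, seed = 1,
    causal = causal_spec(model = "wt_carrier_het_affected")))
  expect_equal(sim$variants$`294`, "het")
  expect_equal(sim$variants$`367`, "hom_ref")
  expect_equal(sim$variants$`407`, "hom_ref")
  expect_equal(sim$variants$`408`, "het")
})

test_that("an empty simulation still writes a valid 10-sample VCF", {
  sim <- simulate_cosegregation(sim_config(n_background = 0, seed = 2,
                                           causal = NULL))
  expect_equal(nrow(sim$variants), 0)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  v <- read_vcf(paths[["vcf"]])
  expect_equal(nrow(v), 0)
  expect_equal(vcf_samples(v), rd6_family()$member_id)
})

test_that("the seed fully determines the output, byte for byte", {
  cfg <- sim_config(n_background = 300, seed = 1234,
                    genotyping_error_rate = 0.02, missing_rate = 0.02)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_cosegregation(cfg), d1)
  write_simulation(simulate_cosegregation(cfg), d2)
  for (f in c("sim.ped", "sim.vcf", "sim.truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # a different seed changes the data
  write_simulation(simulate_cosegregation(
    sim_config(n_background = 300, seed = 1235)), d2)
  expect_false(identical(readLines(file.path(d1, "sim.vcf")),
                         readLines(file.path(d2, "sim.vcf"))))
})

test_that("zero-error gene dropping is Mendelian-consistent at every variant", {
  sim <- simulate_cosegregation(sim_config(n_background = 300, seed = 9))
  ped <- sim$pedigree
  cls <- sim$truth$classes
  kids <- which(!is.na(ped$father_id))
  for (i in seq_len(nrow(cls))) {
    for (j in kids) {
      expect_true(oracle_trio_ok(cls[i, ped$member_id[j]],
                                 cls[i, ped$father_id[j]],
                                 cls[i, ped$mother_id[j]]))
    }
  }
})

test_that("an affection pattern impossible under the causal model is refused", {
  # under the dominant-style model, unaffected parents are hom_ref and
  # cannot transmit the alternate allele an affected child would need
  ped <- trio_pedigree(child_affection = "affected")
  expect_error(
    simulate_cosegregation(sim_config(
      pedigree = ped, n_background = 0, seed = 1,
      causal = causal_spec(model = "wt_carrier_het_affected"))),
    "impossible.*C")
  # the same family is feasible under the recessive-style model
  sim <- simulate_cosegregation(sim_config(
    pedigree = ped, n_background = 0, seed = 1,
    causal = causal_spec(model = "het_carrier_hom_affected")))
  expect_equal(nrow(sim$variants), 1)
})

test_that("configuration validation rejects out-of-range rates", {
  expect_error(sim_config(genotyping_error_rate = 1.5), "\\[0, 1\\)")
  expect_error(sim_config(missing_rate = -0.1), "\\[0, 1\\)")
  expect_error(sim_config(n_background = -5), ">= 0")
  ped <- rd6_family()
  ped$sex[3] <- "unknown"
  expect_error(sim_config(pedigree = ped), "sex")
})

test_that("background annotation proportions are respected", {
  sim <- simulate_cosegregation(sim_config(
    n_background = 500, seed = 31,
    ann_proportions = c(protein_coding = 0, intronic = 1, intergenic = 0)))
  bg <- sim$variants[sim$variants$site_id != sim$truth$causal_site_id, ]
  classes <- vapply(bg$ann, classify_consequence, character(1))
  expect_true(all(classes == "intronic"))

  sim2 <- simulate_cosegregation(sim_config(n_background = 10000, seed = 32,
                                            causal = NULL))
  classes2 <- vapply(sim2$variants$ann, classify_consequence, character(1))
  counts <- table(factor(classes2, levels = c("protein_coding", "intronic",
                                              "intergenic")))
  expected <- 10000 * c(0.01, 0.33, 0.66)
  sds <- sqrt(10000 * c(0.01, 0.33, 0.66) * (1 - c(0.01, 0.33, 0.66)))
  expect_true(all(abs(as.integer(counts) - expected) <= 3 * sds))
})

test_that("the causal record's annotation template survives the pipeline", {
  sim <- simulate_cosegregation(sim_config(n_background = 50, seed = 12))
  i <- which(sim$variants$site_id == sim$truth$causal_site_id)
  ann <- sim$variants$ann[[i]]
  expect_equal(ann$gene, "Pde6b")
  expect_equal(ann$hgvs_c, "c.1678C>T")
  expect_equal(classify_consequence(ann), "protein_coding")
})

test_that("genotyping error degrades strict-policy causal recovery as (1-e)^m", {
  eps <- 0.1
  n_members <- nrow(rd6_family())
  seeds <- 1:300
  recovered <- vapply(seeds, function(s) {
    sim <- simulate_cosegregation(sim_config(
      n_background = 0, seed = s, genotyping_error_rate = eps,
      corrupt_causal = TRUE))
    res <- segregate(sim$variants, sim$pedigree,
                     "het_carrier_hom_affected")
    sim$truth$causal_site_id %in% res$surviving$site_id
  }, logical(1))
  p_clean <- (1 - eps)^n_members
  se <- sqrt(p_clean * (1 - p_clean) / length(seeds))
  expect_lt(abs(mean(recovered) - p_clean), 3 * se)
})

test_that("unrelated-panel mode draws every member independently under HWE", {
  ped <- rd6_family()
  sim <- simulate_cosegregation(sim_config(
    pedigree = ped, n_background = 4000, seed = 55, causal = NULL,
    founder_af = af_fixed(0.5), mode = "unrelated_panel"))
  # at q = 0.5 each member is het with probability 1/2 independently
  het_frac <- mean(sim$truth$classes == "het")
  expect_lt(abs(het_frac - 0.5), 3 * sqrt(0.25 / length(sim$truth$classes)))
  # offspring in this mode need not be Mendelian-consistent with parents:
  # dropping genotypes independently breaks transmission on purpose
  kid <- ped$member_id[!is.na(ped$father_id)][1]
  inconsistent <- sum(!vapply(seq_len(nrow(sim$truth$classes)), function(i)
    oracle_trio_ok(sim$truth$classes[i, kid],
                   sim$truth$classes[i, "294"],
                   sim$truth$classes[i, "367"]), logical(1)))
  expect_gt(inconsistent, 0)
})
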