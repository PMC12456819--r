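study_requirements <- function(model = "het_carrier_hom_affected") {
  derive_requirements(rd6_family(), model)
}

study_genotypes <- function(affected_class, unaffected_class) {
  ped <- rd6_family()
  setNames(ifelse(ped$affection == "affected", affected_class,
                  unaffected_class), ped$member_id)
}

test_that("matches_model applies exact pattern semantics", {
  req <- study_requirements()
  g <- study_genotypes("hom_alt", "het")
  expect_true(matches_model(g, req)$match)

  g2 <- g
  g2[["408"]] <- "het"
  res <- matches_model(g2, req)
  expect_false(res$match)
  expect_equal(res$reason, "pattern-mismatch")

  g3 <- g
  g3[["367"]] <- "missing"
  strict <- matches_model(g3, req, missing_policy = "strict")
  expect_false(strict$match)
  expect_equal(strict$reason, "missing-genotype")
  lenient <- matches_model(g3, req, missing_policy = "ignore_sample")
  expect_true(lenient$match)

  g4 <- g
  g4[["294"]] <- "other"
  expect_equal(matches_model(g4, req)$reason, "other-class")
  expect_false(matches_model(g4, req,
                             missing_policy = "ignore_sample")$match)

  all_missing <- setNames(rep("missing", length(g)), names(g))
  expect_false(matches_model(all_missing, req,
                             missing_policy = "ignore_sample")$match)

  expect_error(matches_model(g[-1], req), "absent")
})

test_that("max_discordant relaxes the exact match by the stated count", {
  req <- study_requirements()
  g <- study_genotypes("hom_alt", "het")
  g[["408"]] <- "het"
  expect_false(matches_model(g, req, max_discordant = 0L)$match)
  expect_true(matches_model(g, req, max_discordant = 1L)$match)
  g[["409"]] <- "het"
  expect_false(matches_model(g, req, max_discordant = 1L)$match)
})

test_that("the filter recovers a planted causal variant and matches a brute-force oracle", {
  sim <- simulate_cosegregation(sim_config(n_background = 1000, seed = 77))
  res <- segregate(sim$variants, sim$pedigree, "het_carrier_hom_affected")
  expect_true(sim$truth$causal_site_id %in% res$surviving$site_id)
  oracle <- oracle_filter(sim$variants, sim$pedigree,
                          list(affected = "hom_alt", unaffected = "het"))
  expect_setequal(res$surviving$site_id, oracle)
  # input order preserved
  expect_identical(res$surviving$site_id,
                   sim$variants$site_id[sim$variants$site_id %in% oracle])
})

test_that("every variant is either a survivor or a counted exclusion", {
  for (seed in c(5, 6)) {
    sim <- simulate_cosegregation(sim_config(
      n_background = 400, seed = seed, genotyping_error_rate = 0.05,
      missing_rate = 0.05))
    for (policy in c("strict", "ignore_sample")) {
      res <- segregate(sim$variants, sim$pedigree,
                       "het_carrier_hom_affected", missing_policy = policy)
      expect_equal(sum(res$exclusions) + res$n_surviving, res$n_input)
      expect_equal(sum(res$per_class_counts), res$n_surviving)
      expect_equal(res$n_surviving, nrow(res$surviving))
    }
  }
})

test_that("strict survivors are a subset of ignore_sample survivors", {
  sim <- simulate_cosegregation(sim_config(
    n_background = 800, seed = 13, missing_rate = 0.1))
  strict <- segregate(sim$variants, sim$pedigree,
                      "het_carrier_hom_affected", missing_policy = "strict")
  lenient <- segregate(sim$variants, sim$pedigree,
                       "het_carrier_hom_affected",
                       missing_policy = "ignore_sample")
  expect_true(all(strict$surviving$site_id %in% lenient$surviving$site_id))
})

test_that("model-1 and model-2 survivors are disjoint on fully-called data", {
  sim <- simulate_cosegregation(sim_config(n_background = 600, seed = 21))
  r1 <- segregate(sim$variants, sim$pedigree, "het_carrier_hom_affected")
  r2 <- segregate(sim$variants, sim$pedigree, "wt_carrier_het_affected")
  expect_length(intersect(r1$surviving$site_id, r2$surviving$site_id), 0)
})

test_that("segregation requires pedigree samples to exist in the data", {
  sim <- simulate_cosegregation(sim_config(n_background = 10, seed = 3))
  extra <- rd6_family()
  extra$member_id[extra$member_id == "294"] <- "999"
  extra$father_id[!is.na(extra$father_id)] <- "999"
  expect_error(segregate(sim$variants, extra, "het_carrier_hom_affected"),
               "missing from the VCF|absent")
})

test_that("null survival follows the Hardy-Weinberg closed form", {
  expect_equal(expected_null_survival(0.5, n_hom_alt = 1, n_het = 1), 0.125)
  expect_equal(expected_null_survival(0.5, n_hom_alt = 2, n_het = 2),
               0.015625)
  expect_error(expected_null_survival(0, n_hom_alt = 1), "inside")
  expect_error(expected_null_survival(1.2, n_hom_alt = 1), "inside")
  expect_error(expected_null_survival(0.5), "at least one")
})

test_that("closed-form null survival agrees with Monte-Carlo genotype draws", {
  withr::local_seed(99)
  q <- 0.3
  hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  draw_matches <- function(n_vec, a, h) {
    hom_alt_ok <- matrix(sample(0:2, n_vec * a, TRUE, prob = hwe),
                         ncol = a) == 2
    het_ok <- matrix(sample(0:2, n_vec * h, TRUE, prob = hwe),
                     ncol = h) == 1
    sum(rowSums(hom_alt_ok) == a & rowSums(het_ok) == h)
  }
  # moderate requirement: non-trivial match probability
  n_vec <- 2e5
  p <- expected_null_survival(q, n_hom_alt = 2, n_het = 2)
  obs <- draw_matches(n_vec, 2, 2)
  expect_lt(abs(obs - n_vec * p), 3 * sqrt(n_vec * p * (1 - p)) + 1e-9)
  # the full family-sized requirement: survival is vanishingly rare
  n_vec <- 1e6
  p10 <- expected_null_survival(q, n_hom_alt = 6, n_het = 4)
  obs10 <- draw_matches(n_vec, 6, 4)
  expect_lt(abs(obs10 - n_vec * p10),
            3 * sqrt(n_vec * p10 * (1 - p10)) + 1)
})

test_that("tidy and glance summarize a segregation result consistently", {
  sim <- simulate_cosegregation(sim_config(n_background = 200, seed = 8))
  res <- segregate(sim$variants, sim$pedigree, "het_carrier_hom_affected")
  td <- tidy(res)
  gl <- glance(res)
  expect_equal(nrow(td), res$n_surviving)
  expect_equal(gl$n_input, 201)
  expect_equal(gl$n_surviving, res$n_surviving)
  expect_equal(gl$n_protein_coding + gl$n_intronic + gl$n_intergenic +
                 gl$n_other_class, gl$n_surviving)
  expect_true(all(c("model_id", "site_id", "consequence", "gene") %in%
                    names(td)))
  expect_s3_class(autoplot(res), "ggplot")
})
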