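study_ped_path <- system.file("extdata", "rd6_family.ped", package = "cosegr")

test_that("the packaged family fixture parses to the published structure", {
  ped <- read_ped(study_ped_path)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 10)
  expect_equal(count_members(ped, founders = TRUE), 2)
  expect_equal(count_members(ped, founders = FALSE), 8)
  expect_equal(count_members(ped, sex = "male", affection = "affected",
                             founders = FALSE), 4)
  expect_equal(count_members(ped, sex = "female", affection = "affected",
                             founders = FALSE), 1)
  expect_equal(ped$affection[ped$member_id == "294"], "affected")
  expect_equal(ped$affection[ped$member_id == "367"], "unaffected")
  expect_true(all(ped$sequenced))
  expect_identical(ped, rd6_family())
  expect_s3_class(autoplot(ped), "ggplot")
})

test_that("degenerate pedigrees parse: one founder, empty filters", {
  p <- withr::local_tempfile(fileext = ".ped")
  writeLines("FAM\tX\t0\t0\t1\t2", p)
  ped <- read_ped(p)
  expect_equal(nrow(ped), 1)
  expect_equal(count_members(ped, founders = TRUE), 1)
  expect_equal(count_members(ped, founders = FALSE), 0)
  empty <- as_pedigree(tibble::tibble(
    member_id = character(), father_id = character(),
    mother_id = character(), sex = character(), affection = character()))
  expect_equal(count_members(empty), 0)
})

test_that("pedigree validation rejects malformed files", {
  write_ped_lines <- function(lines) {
    p <- withr::local_tempfile(fileext = ".ped",
                               .local_envir = parent.frame())
    writeLines(lines, p)
    p
  }
  # individual listed as its own father: a cycle
  expect_error(read_ped(write_ped_lines(c(
    "F\tA\tA\tB\t1\t2", "F\tB\t0\t0\t2\t1"))), "cycle")
  # two-member parentage loop
  expect_error(read_ped(write_ped_lines(c(
    "F\tA\tB\tC\t1\t2", "F\tB\tA\tC\t1\t1", "F\tC\t0\t0\t2\t1"))),
    "one parent|cycle")
  expect_error(read_ped(write_ped_lines(c(
    "F\tA\t0\t0\t1\t2", "F\tA\t0\t0\t1\t1"))), "duplicate")
  expect_error(read_ped(write_ped_lines(
    "F\tA\tP\tQ\t1\t2")), "referenced but not present")
  # referenced father with unknown sex
  expect_error(read_ped(write_ped_lines(c(
    "F\tP\t0\t0\t0\t1", "F\tQ\t0\t0\t2\t1", "F\tA\tP\tQ\t1\t2"))),
    "not recorded as male")
  # one parent present, the other absent
  expect_error(read_ped(write_ped_lines(c(
    "F\tP\t0\t0\t1\t1", "F\tA\tP\t0\t1\t2"))), "one parent")
})

test_that("affection and sequenced encodings follow the PED dialect", {
  p <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F\tA\t0\t0\t1\t-9\t1", "F\tB\t0\t0\t2\t0\t0",
               "F\tC\tA\tB\t1\t2\t1"), p)
  ped <- read_ped(p)
  expect_equal(ped$affection, c("unknown", "unknown", "affected"))
  expect_equal(ped$sequenced, c(TRUE, FALSE, TRUE))
})

test_that("PED write/read round-trips the pedigree exactly", {
  ped <- rd6_family(unsequenced = c("407", "382"))
  p <- withr::local_tempfile(fileext = ".ped")
  write_ped(ped, p)
  expect_identical(read_ped(p), ped)
  # serialization is whitespace-normalized but content-stable
  expect_identical(readLines(p), {
    p2 <- withr::local_tempfile(fileext = ".ped")
    write_ped(read_ped(p), p2)
    readLines(p2)
  })
})

test_that("requirement derivation maps affection to the model's classes", {
  ped <- rd6_family()
  req1 <- derive_requirements(ped, "het_carrier_hom_affected")
  expect_setequal(req1$member_id, ped$member_id)
  affected <- c("294", "408", "409", "410", "411", "381")
  for (m in affected) {
    expect_equal(req1$required[[which(req1$member_id == m)]], "hom_alt")
  }
  for (m in setdiff(ped$member_id, affected)) {
    expect_equal(req1$required[[which(req1$member_id == m)]], "het")
  }
  req2 <- derive_requirements(ped, "wt_carrier_het_affected")
  expect_true(all(vapply(which(req2$affection == "affected"),
                         function(i) req2$required[[i]] == "het",
                         logical(1))))
  expect_true(all(vapply(which(req2$affection == "unaffected"),
                         function(i) req2$required[[i]] == "hom_ref",
                         logical(1))))
})

test_that("requirements cover exactly the sequenced, known-affection members", {
  ped <- rd6_family(unsequenced = "412")
  ped$affection[ped$member_id == "407"] <- "unknown"
  req <- suppressMessages(derive_requirements(ped, "het_carrier_hom_affected"))
  expect_false("412" %in% req$member_id)
  expect_false("407" %in% req$member_id)
  expect_equal(attr(req, "excluded"), "407")
  expect_equal(anyDuplicated(req$member_id), 0)

  none <- rd6_family()
  none$sequenced <- FALSE
  expect_error(derive_requirements(none, "het_carrier_hom_affected"),
               "no sequenced")
})

test_that("requirement sets of the two built-in models are pointwise disjoint", {
  ped <- rd6_family()
  r1 <- derive_requirements(ped, "het_carrier_hom_affected")
  r2 <- derive_requirements(ped, "wt_carrier_het_affected")
  for (i in seq_len(nrow(r1))) {
    expect_length(intersect(r1$required[[i]], r2$required[[i]]), 0)
  }
})

test_that("inheritance_model validates its requirement sets", {
  expect_error(inheritance_model("nonsense_model"), "unknown model")
  expect_error(inheritance_model("m", required = list(affected = "hom_alt")),
               "both")
  expect_error(inheritance_model("m", required = list(
    affected = "hom_alt", unaffected = "frog")), "unknown genotype class")
  expect_warning(inheritance_model("m", required = list(
    affected = c("het", "hom_alt"), unaffected = "het")), "overlap")
})
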