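Package: cosegr
Title: Pedigree-Based Variant Cosegregation Filtering and Gene-Dropping
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers candidate causal variants hidden in families by exact
    genotype-pattern filtering of multi-sample VCF calls against explicit
    inheritance models derived from a pedigree with affection status, followed
    by annotation-based consequence triage, HGVS coding-position arithmetic to
    verify missense candidates, and exact concordance testing of a candidate
    in an independent confirmation cohort. A gene-dropping simulator generates
    pedigree-consistent synthetic PED and VCF data with a planted causal
    variant so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
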