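#' Read a PED pedigree file
#'
#' Parses a header-less, whitespace-delimited PED file in the standard
#' six-column dialect (family, individual, father, mother, sex, phenotype)
#' into a validated pedigree tibble. An optional seventh column flags whether
#' an individual was sequenced (1) or not (0); when absent, every member is
#' treated as sequenced.
#'
#' Encodings follow the common PLINK conventions: sex 1 = male, 2 = female,
#' 0 = unknown; phenotype 2 = affected, 1 = unaffected, 0 or -9 = unknown.
#' Absent parents are encoded as `0`.
#'
#' @param path Path to a PED file (or a connection).
#' @return A `pedigree` tibble with one row per member, in file order, and
#'   columns `family_id`, `member_id`, `father_id`, `mother_id` (`NA` for
#'   founders), `sex` (`"male"`, `"female"`, `"unknown"`), `affection`
#'   (`"affected"`, `"unaffected"`, `"unknown"`), `sequenced` (logical) and
#'   a derived `generation` (0 for founders).
#' @examples
#' ped <- read_ped(system.file("extdata", "rd6_family.ped", package = "cosegr"))
#' count_members(ped, sex = "male", affection = "affected", founders = FALSE)
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 6 || ncol(raw) > 7) {
    abort(sprintf("PED file must have 6 or 7 columns, found %d", ncol(raw)))
  }
  sequenced <- if (ncol(raw) == 7) raw[[7]] == "1" else rep(TRUE, nrow(raw))
  members <- tibble(
    family_id = raw[[1]],
    member_id = raw[[2]],
    father_id = dplyr::na_if(raw[[3]], "0"),
    mother_id = dplyr::na_if(raw[[4]], "0"),
    sex = decode_sex(raw[[5]]),
    affection = decode_affection(raw[[6]]),
    sequenced = sequenced
  )
  as_pedigree(members)
}

decode_sex <- function(x) {
  dplyr::case_match(x, "1" ~ "male", "2" ~ "female", .default = "unknown")
}

decode_affection <- function(x) {
  dplyr::case_match(x, "2" ~ "affected", "1" ~ "unaffected",
                    .default = "unknown")
}

#' Construct a validated pedigree from a data frame
#'
#' Validates member uniqueness, parent references, parent sex, the
#' founder/non-founder contract (both parents present or both absent) and
#' acyclicity, then derives each member's generation (founders are
#' generation 0).
#'
#' @param members A data frame with columns `member_id`, `father_id`,
#'   `mother_id`, `sex`, `affection`; optional `family_id` and `sequenced`
#'   (default `"FAM1"` and `TRUE`).
#' @return A `pedigree` tibble (see [read_ped()]).
#' @export
as_pedigree <- function(members) {
  members <- as_tibble(members)
  if (!"family_id" %in% names(members)) members$family_id <- "FAM1"
  if (!"sequenced" %in% names(members)) members$sequenced <- TRUE
  required_cols <- c("member_id", "father_id", "mother_id", "sex", "affection")
  missing_cols <- setdiff(required_cols, names(members))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }

  dup <- members$member_id[duplicated(members$member_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate member id(s): ", paste(unique(dup), collapse = ", ")))
  }

  has_father <- !is.na(members$father_id)
  has_mother <- !is.na(members$mother_id)
  if (any(has_father != has_mother)) {
    bad <- members$member_id[has_father != has_mother]
    abort(paste0("member(s) with exactly one parent recorded: ",
                 paste(bad, collapse = ", ")))
  }

  parents <- unique(c(members$father_id[has_father],
                      members$mother_id[has_mother]))
  absent <- setdiff(parents, members$member_id)
  if (length(absent) > 0) {
    abort(paste0("parent id(s) referenced but not present: ",
                 paste(absent, collapse = ", ")))
  }

  sex_of <- setNames(members$sex, members$member_id)
  bad_father <- unique(members$father_id[has_father &
                         sex_of[members$father_id] != "male"])
  bad_father <- bad_father[!is.na(bad_father)]
  if (length(bad_father) > 0) {
    abort(paste0("father id(s) not recorded as male: ",
                 paste(bad_father, collapse = ", ")))
  }
  bad_mother <- unique(members$mother_id[has_mother &
                         sex_of[members$mother_id] != "female"])
  bad_mother <- bad_mother[!is.na(bad_mother)]
  if (length(bad_mother) > 0) {
    abort(paste0("mother id(s) not recorded as female: ",
                 paste(bad_mother, collapse = ", ")))
  }

  members$generation <- derive_generations(members)

  members <- members[, c("family_id", "member_id", "father_id", "mother_id",
                         "sex", "affection", "sequenced", "generation")]
  class(members) <- c("pedigree", class(tibble()))
  members
}

# Iterative longest-path generation assignment; failure to converge means the
# parentage graph has a cycle (including self-parenting).
derive_generations <- function(members) {
  n <- nrow(members)
  gen <- rep(NA_integer_, n)
  names(gen) <- members$member_id
  is_founder <- is.na(members$father_id)
  gen[is_founder] <- 0L
  for (iter in seq_len(n + 1L)) {
    changed <- FALSE
    for (i in which(!is_founder)) {
      pg <- gen[c(members$father_id[i], members$mother_id[i])]
      if (!anyNA(pg)) {
        g <- max(pg) + 1L
        if (is.na(gen[i]) || gen[i] != g) {
          gen[i] <- g
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  if (anyNA(gen)) {
    abort(paste0("pedigree parentage contains a cycle involving: ",
                 paste(names(gen)[is.na(gen)], collapse = ", ")))
  }
  unname(gen)
}

#' Write a pedigree to a PED file
#'
#' Serializes a pedigree back to the 7-column PED dialect read by
#' [read_ped()] (tab-delimited, no header, sequenced flag as the seventh
#' column). Reading the result back reproduces the pedigree exactly.
#'
#' @param pedigree A `pedigree` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(pedigree, path) {
  sex_code <- dplyr::case_match(pedigree$sex, "male" ~ "1", "female" ~ "2",
                                .default = "0")
  aff_code <- dplyr::case_match(pedigree$affection, "affected" ~ "2",
                                "unaffected" ~ "1", .default = "0")
  out <- data.frame(
    pedigree$family_id, pedigree$member_id,
    ifelse(is.na(pedigree$father_id), "0", pedigree$father_id),
    ifelse(is.na(pedigree$mother_id), "0", pedigree$mother_id),
    sex_code, aff_code, ifelse(pedigree$sequenced, "1", "0")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count pedigree members matching filters
#'
#' @param pedigree A `pedigree` tibble.
#' @param sex Optional filter: `"male"`, `"female"` or `"unknown"`.
#' @param affection Optional filter: `"affected"`, `"unaffected"` or
#'   `"unknown"`.
#' @param founders Optional logical filter: `TRUE` counts only founders,
#'   `FALSE` only non-founders.
#' @return Integer count of members matching every supplied filter.
#' @export
count_members <- function(pedigree, sex = NULL, affection = NULL,
                          founders = NULL) {
  keep <- rep(TRUE, nrow(pedigree))
  if (!is.null(sex)) keep <- keep & pedigree$sex == sex
  if (!is.null(affection)) keep <- keep & pedigree$affection == affection
  if (!is.null(founders)) {
    keep <- keep & (is.na(pedigree$father_id) == founders)
  }
  sum(keep)
}

#' @export
print.pedigree <- function(x, ...) {
  n_founder <- count_members(x, founders = TRUE)
  cat(sprintf("# A pedigree: %d members (%d founders, %d affected)\n",
              nrow(x), n_founder, count_members(x, affection = "affected")))
  NextMethod()
}

#' Plot a pedigree diagram
#'
#' Draws the family as a standard pedigree diagram: squares for males,
#' circles for females, filled symbols for affected members, one row per
#' generation, with lines joining offspring to the midpoint of their
#' parents.
#'
#' @param object A `pedigree` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pedigree <- function(object, ...) {
  layout <- object |>
    dplyr::group_by(.data$generation) |>
    dplyr::mutate(x = seq_along(.data$member_id) -
                    (dplyr::n() + 1) / 2) |>
    dplyr::ungroup() |>
    dplyr::mutate(y = -.data$generation)
  pos_x <- setNames(layout$x, layout$member_id)
  pos_y <- setNames(layout$y, layout$member_id)
  kids <- layout[!is.na(layout$father_id), ]
  segs <- tibble(
    x = (pos_x[kids$father_id] + pos_x[kids$mother_id]) / 2,
    y = (pos_y[kids$father_id] + pos_y[kids$mother_id]) / 2,
    xend = pos_x[kids$member_id],
    yend = pos_y[kids$member_id]
  )
  ggplot2::ggplot(layout, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey50"
    ) +
    ggplot2::geom_point(
      ggplot2::aes(shape = .data$sex, fill = .data$affection),
      size = 8, colour = "black"
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$member_id),
                       vjust = 3.2, size = 3) +
    ggplot2::scale_shape_manual(
      values = c(male = 22, female = 21, unknown = 23)) +
    ggplot2::scale_fill_manual(
      values = c(affected = "black", unaffected = "white",
                 unknown = "grey80")) +
    ggplot2::theme_void() +
    ggplot2::expand_limits(y = c(min(layout$y) - 0.5, 0.5))
}
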