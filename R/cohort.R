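# Cohort construction: applies the demographic eligibility filters to a pedigree
# and assembles the per-proband analysis table for one of the four fitness
# outcomes. Every filter step is counted so attrition can be audited against
# generative truth.

OUTCOMES <- c("survival15", "longevity", "marriage", "lbs")

#' Build an analysis cohort for one fitness outcome
#'
#' Starting from every individual with a computed WMAMA, applies in order:
#' (1) born before 1900; (2) father's and both grandfathers' ages known
#' (great-grandfathers optional); (3) social class known — taken from the
#' father's record for `survival15`, `longevity` and `marriage`, and from the
#' individual's own record for `lbs`; then the outcome-specific filters:
#'
#' * `survival15`: excludes individuals who emigrated before age 15. Outcome
#'   is 1 if the individual reached 15 (death year absent or at least 15
#'   years after birth).
#' * `longevity`: survivors to 15 with a known death year and no emigration.
#'   Outcome is whole years lived beyond 15.
#' * `marriage`: survivors to 15 followed to at least age 45 (females) / 50
#'   (males) — death or emigration before that age excludes. Outcome is
#'   whether the individual ever married (analyse the sexes separately).
#' * `lbs`: ever-married individuals who survived to at least 45/50.
#'   Outcome is the number of children born.
#'
#' Rows with missing required covariates (parish, twin, first-born status,
#' maternal age, sex, birth year) are removed last. The per-filter attrition
#' is attached as `attr(, "attrition")`.
#'
#' @param pedigree A pedigree tibble ([as_pedigree()]).
#' @param outcome One of `"survival15"`, `"longevity"`, `"marriage"`, `"lbs"`.
#' @param wmama_values Per-proband WMAMA table from [wmama_table()]. Computed
#'   on the fly when omitted.
#' @return A `wmama_cohort` tibble with one row per eligible proband and
#'   columns `proband_id`, `outcome`, `wmama`, `wmama_excl_father`,
#'   `father_age`, `maternal_age`, `parish`, `social_class`, `twin`,
#'   `first_born`, `sex`, `birth_year`, `mother_id`, `death_year`.
#' @export
build_cohort <- function(pedigree, outcome, wmama_values = NULL) {
  if (!outcome %in% OUTCOMES) {
    abort(paste0("Unknown outcome `", outcome, "`; expected one of: ",
                 paste(OUTCOMES, collapse = ", ")))
  }
  if (is.null(wmama_values)) wmama_values <- wmama_table(pedigree)

  fa_idx <- match(pedigree$father_id, pedigree$id)
  mo_idx <- match(pedigree$mother_id, pedigree$id)
  base <- pedigree |>
    transmute(
      proband_id = .data$id,
      sex = .data$sex,
      birth_year = .data$birth_year,
      death_year = .data$death_year,
      emigration_year = .data$emigration_year,
      parish = .data$parish,
      own_class = .data$social_class,
      father_class = pedigree$social_class[fa_idx],
      twin = .data$twin,
      first_born = .data$first_born,
      married = .data$married,
      n_children = .data$n_children,
      mother_id = .data$mother_id,
      maternal_age = .data$birth_year - pedigree$birth_year[mo_idx]
    ) |>
    left_join(wmama_values, by = "proband_id")

  attrition <- list()
  note <- function(tbl, label, prev_n) {
    attrition[[length(attrition) + 1]] <<- tibble(
      filter = label, removed = prev_n - nrow(tbl), remaining = nrow(tbl)
    )
    tbl
  }

  n <- nrow(base)
  tbl <- base |> filter(!is.na(.data$birth_year), .data$birth_year < 1900)
  tbl <- note(tbl, "born before 1900", n)

  n <- nrow(tbl)
  tbl <- tbl |>
    filter(!is.na(.data$wmama), .data$missing_g1 == 0, .data$missing_g2 == 0)
  tbl <- note(tbl, "father and both grandfathers' ages known", n)

  class_col <- if (outcome == "lbs") "own_class" else "father_class"
  n <- nrow(tbl)
  tbl <- tbl |>
    mutate(social_class = .data[[class_col]]) |>
    filter(!is.na(.data$social_class))
  tbl <- note(tbl, paste0("social class known (", class_col, ")"), n)

  age_at_death <- tbl$death_year - tbl$birth_year
  age_at_emig <- tbl$emigration_year - tbl$birth_year
  survived15 <- is.na(age_at_death) | age_at_death >= 15
  followup_age <- ifelse(tbl$sex == "female", 45, 50)

  if (outcome == "survival15") {
    n <- nrow(tbl)
    keep <- is.na(age_at_emig) | age_at_emig >= 15
    tbl <- tbl[keep, ]
    tbl <- note(tbl, "no emigration before age 15", n)
    tbl$outcome <- as.integer(survived15[keep])
  } else if (outcome == "longevity") {
    n <- nrow(tbl)
    keep <- survived15 & !is.na(age_at_death) & is.na(tbl$emigration_year)
    tbl <- tbl[keep, ]
    tbl <- note(tbl, "survived to 15, death year known, non-emigrant", n)
    tbl$outcome <- floor(tbl$death_year - tbl$birth_year) - 15
  } else if (outcome == "marriage") {
    n <- nrow(tbl)
    keep <- survived15
    tbl <- tbl[keep, ]
    tbl <- note(tbl, "survived to 15", n)
    n <- nrow(tbl)
    age_d <- tbl$death_year - tbl$birth_year
    age_e <- tbl$emigration_year - tbl$birth_year
    fup <- ifelse(tbl$sex == "female", 45, 50)
    keep <- (is.na(age_d) | age_d >= fup) & (is.na(age_e) | age_e >= fup)
    tbl <- tbl[keep, ]
    tbl <- note(tbl, "followed to age 45 (f) / 50 (m)", n)
    n <- nrow(tbl)
    tbl <- tbl |> filter(!is.na(.data$married))
    tbl <- note(tbl, "marriage status known", n)
    tbl$outcome <- as.integer(tbl$married)
  } else { # lbs
    n <- nrow(tbl)
    keep <- !is.na(tbl$married) & tbl$married
    tbl <- tbl[keep, ]
    tbl <- note(tbl, "ever married", n)
    n <- nrow(tbl)
    age_d <- tbl$death_year - tbl$birth_year
    fup <- ifelse(tbl$sex == "female", 45, 50)
    keep <- is.na(age_d) | age_d >= fup
    tbl <- tbl[keep, ]
    tbl <- note(tbl, "survived to age 45 (f) / 50 (m)", n)
    n <- nrow(tbl)
    tbl <- tbl |> filter(!is.na(.data$n_children))
    tbl <- note(tbl, "breeding success known", n)
    tbl$outcome <- as.integer(tbl$n_children)
  }

  n <- nrow(tbl)
  tbl <- tbl |>
    filter(!is.na(.data$parish), !is.na(.data$twin), !is.na(.data$first_born),
           !is.na(.data$maternal_age), !is.na(.data$sex))
  tbl <- note(tbl, "complete covariates", n)

  out <- tbl |>
    select("proband_id", "outcome", "wmama", "wmama_excl_father",
           "father_age", "maternal_age", "parish", "social_class", "twin",
           "first_born", "sex", "birth_year", "mother_id", "death_year")
  attr(out, "attrition") <- bind_rows(attrition)
  attr(out, "outcome_name") <- outcome
  class(out) <- c("wmama_cohort", class(out))
  out
}

#' Per-filter attrition of a cohort
#'
#' @param cohort A cohort from [build_cohort()].
#' @return Tibble of `filter`, `removed`, `remaining`.
#' @export
attrition <- function(cohort) {
  out <- attr(cohort, "attrition")
  if (is.null(out)) abort("`cohort` carries no attrition record.")
  out
}

#' Write a cohort with its attrition sidecar
#'
#' Writes the cohort as delimited text and the attrition table alongside it
#' as `<path>.attrition.tsv`.
#'
#' @param cohort A cohort from [build_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(as_tibble(cohort), path, na = "NA")
  readr::write_tsv(attrition(cohort), paste0(path, ".attrition.tsv"), na = "NA")
  invisible(path)
}
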