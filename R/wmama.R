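# The weighted mean age of male ancestors (WMAMA):
#   m = sum(a_i * r_i) / sum(r_i)
# over the proband's known male ancestors up to great-grandfather level, with
# coefficients of relationship r = 0.5 (father), 0.25 (grandfather),
# 0.125 (great-grandfather). Unknown ancestors drop out of both sums.

#' Compute the weighted mean age of male ancestors
#'
#' @param ancestors An `ancestor_ages` object from [collect_male_ancestors()].
#' @param variant `"full"` uses every known ancestor; `"exclude_father"`
#'   drops generation 1; `"father_only"` keeps only the father. After dropping,
#'   the remaining weights are renormalized.
#' @return A one-row tibble with `m` (years), `variant`, `n_used` and
#'   `weight_sum`.
#' @examples
#' ped <- as_pedigree(tibble::tibble(
#'   id = c("gf", "gm", "f", "m", "p"),
#'   sex = c("male", "female", "male", "female", "male"),
#'   father_id = c(NA, NA, "gf", NA, "f"),
#'   mother_id = c(NA, NA, "gm", NA, "m"),
#'   birth_year = c(1790, 1795, 1825, 1828, 1855)
#' ))
#' compute_wmama(collect_male_ancestors(ped, "p"))
#' @export
compute_wmama <- function(ancestors,
                          variant = c("full", "exclude_father", "father_only")) {
  variant <- match.arg(variant)
  stopifnot(inherits(ancestors, "ancestor_ages"))
  e <- ancestors$entries
  e <- switch(variant,
    full = e,
    exclude_father = filter(e, .data$generation > 1),
    father_only = filter(e, .data$generation == 1)
  )
  if (nrow(e) == 0) {
    abort(paste0("No ancestors available for variant `", variant,
                 "` of proband `", ancestors$proband_id, "`."))
  }
  tibble(
    proband_id = ancestors$proband_id,
    m = sum(e$age * e$weight) / sum(e$weight),
    variant = variant,
    n_used = nrow(e),
    weight_sum = sum(e$weight)
  )
}

#' WMAMA for every individual in a pedigree
#'
#' Vectorised equivalent of running [collect_male_ancestors()] plus
#' [compute_wmama()] for each individual: returns the full-variant WMAMA
#' along with the exclude-father variant, the father's age, and
#' missing-ancestor tallies. Individuals with no known male ancestor get
#' `NA` statistics rather than an error.
#'
#' @param pedigree A pedigree tibble.
#' @param max_generations Ancestral depth (1, 2 or 3; default 3).
#' @return A tibble with one row per individual: `proband_id`, `wmama`,
#'   `wmama_excl_father`, `father_age`, `n_used`, `weight_sum`, and
#'   `missing_g1`, `missing_g2`, `missing_g3` tallies.
#' @export
wmama_table <- function(pedigree, max_generations = 3) {
  stopifnot(max_generations %in% 1:3)
  id <- pedigree$id
  by <- pedigree$birth_year
  fa <- match(pedigree$father_id, id)
  mo <- match(pedigree$mother_id, id)
  zero <- function(x) ifelse(is.na(x), 0, x)
  # ages at fathering the next lineage member, per generation:
  # a1 father->proband; grandfathers are the parents' a1; the four
  # great-grandfathers are the parents' grandfather entries
  a1 <- by - by[fa]
  gf_f <- a1[fa]
  gf_m <- a1[mo]
  a2_sum <- zero(gf_f) + zero(gf_m)
  a2_n <- (!is.na(gf_f)) + (!is.na(gf_m))
  a3_sum <- ifelse(is.na(fa), 0, zero(a2_sum[fa])) +
    ifelse(is.na(mo), 0, zero(a2_sum[mo]))
  a3_n <- ifelse(is.na(fa), 0L, zero(a2_n[fa])) +
    ifelse(is.na(mo), 0L, zero(a2_n[mo]))
  if (max_generations < 3) {
    a3_sum <- rep(0, length(by)); a3_n <- rep(0L, length(by))
  }
  if (max_generations < 2) {
    a2_sum <- rep(0, length(by)); a2_n <- rep(0L, length(by))
  }
  num_full <- 0.5 * zero(a1) + 0.25 * a2_sum + 0.125 * a3_sum
  den_full <- 0.5 * (!is.na(a1)) + 0.25 * a2_n + 0.125 * a3_n
  den_excl <- 0.25 * a2_n + 0.125 * a3_n
  tibble(
    proband_id = id,
    wmama = ifelse(den_full > 0, num_full / den_full, NA_real_),
    wmama_excl_father = ifelse(den_excl > 0,
                               (0.25 * a2_sum + 0.125 * a3_sum) / den_excl,
                               NA_real_),
    father_age = a1,
    n_used = as.integer((!is.na(a1)) + a2_n + a3_n),
    weight_sum = den_full,
    missing_g1 = as.integer(is.na(a1)),
    missing_g2 = if (max_generations >= 2) as.integer(2L - a2_n) else
      NA_integer_,
    missing_g3 = if (max_generations >= 3) as.integer(4L - a3_n) else
      NA_integer_
  )
}

#' Expected share of the ancestral-age signal per generation
#'
#' The information an ancestral generation contributes to the weighted
#' statistic is proportional to the variance it adds, which halves with each
#' generation: raw weights 1, 0.5 and 0.25 for fathers, grandfathers and
#' great-grandfathers. Normalizing over the generations actually known gives
#' each generation's share; the share of generation 1 is the fraction of
#' signal lost when the father's age is removed.
#'
#' @param known Integer vector of generations with known ages, a subset of
#'   `c(1, 2, 3)`.
#' @param assume_full_counts Reserved; shares assume the full complement of
#'   ancestors (1, 2, 4) within each known generation, which is what the
#'   generation-level weights 1:0.5:0.25 encode.
#' @return A list with `shares` (tibble of `generation`, `weight`, `share`)
#'   and `father_loss` (share of generation 1, 0 if generation 1 unknown).
#' @examples
#' expected_signal_shares(c(1, 2, 3))$father_loss # 0.571...
#' expected_signal_shares(c(1, 2))$father_loss    # 0.666...
#' @export
expected_signal_shares <- function(known = c(1, 2, 3),
                                   assume_full_counts = TRUE) {
  known <- sort(unique(as.integer(known)))
  if (length(known) == 0) abort("`known` must name at least one generation.")
  if (!all(known %in% 1:3)) abort("`known` must be a subset of 1:3.")
  raw <- c(1, 0.5, 0.25)[known]
  shares <- tibble(
    generation = known,
    weight = raw,
    share = raw / sum(raw)
  )
  father_loss <- if (1 %in% known) shares$share[shares$generation == 1] else 0
  list(shares = shares, father_loss = father_loss)
}

#' Mean outcome within WMAMA quartiles
#'
#' Assigns cohort rows to quartiles of the WMAMA distribution (empirical
#' quantiles with linear interpolation; values tied with a cut point fall in
#' the lower quartile) and summarises the outcome per quartile.
#'
#' @param cohort A data frame with a `wmama` column.
#' @param outcome_column Name of the outcome column to summarise.
#' @return A `wmama_quartiles` tibble: `quartile`, `lower_threshold`
#'   (`NA` for the 1st), `mean`, `se`, `n`.
#' @export
quartile_summary <- function(cohort, outcome_column) {
  stopifnot("wmama" %in% names(cohort), outcome_column %in% names(cohort))
  w <- cohort$wmama
  if (length(unique(w)) < 4) {
    abort("Quartiles are undefined: fewer than 4 distinct wmama values.")
  }
  cuts <- quantile(w, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  q <- findInterval(w, cuts, left.open = TRUE) + 1L
  out <- tibble(quartile = q, y = cohort[[outcome_column]]) |>
    group_by(.data$quartile) |>
    summarise(
      mean = mean(.data$y),
      se = sd(.data$y) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(lower_threshold = c(NA_real_, cuts)[.data$quartile]) |>
    select("quartile", "lower_threshold", "mean", "se", "n")
  class(out) <- c("wmama_quartiles", class(out))
  attr(out, "outcome") <- outcome_column
  out
}
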