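# In-code fixtures shared across test files.

# Pedigree with a proband whose 7 male ancestors have designed ages at
# fathering: father 25, grandfathers 30 (paternal) and 35 (maternal),
# all four great-grandfathers 40.
seven_ancestor_pedigree <- function() {
  as_pedigree(tibble::tribble(
    ~id,   ~sex,     ~father_id, ~mother_id, ~birth_year,
    "p",   "male",   "f",        "m",        1860,
    "f",   "male",   "ff",       "fm",       1835,
    "m",   "female", "mf",       "mm",       1838,
    "ff",  "male",   "fff",      NA,         1805,
    "fm",  "female", "fmf",      NA,         1810,
    "mf",  "male",   "mff",      NA,         1803,
    "mm",  "female", "mmf",      NA,         1808,
    "fff", "male",   NA,         NA,         1765,
    "fmf", "male",   NA,         NA,         1770,
    "mff", "male",   NA,         NA,         1763,
    "mmf", "male",   NA,         NA,         1768
  ))
}

# father 30, both grandfathers 35, no great-grandfathers known
three_ancestor_pedigree <- function() {
  as_pedigree(tibble::tribble(
    ~id,  ~sex,     ~father_id, ~mother_id, ~birth_year,
    "p",  "female", "f",        "m",        1860,
    "f",  "male",   "ff",       NA,         1830,
    "m",  "female", "mf",       NA,         1835,
    "ff", "male",   NA,         NA,         1795,
    "mf", "male",   NA,         NA,         1800
  ))
}

# a random valid ancestor-age set (for brute-force oracle comparisons)
random_ancestor_set <- function() {
  gens <- integer(0)
  if (runif(1) < 0.9) gens <- c(gens, 1L)
  gens <- c(gens, rep(2L, rbinom(1, 2, 0.8)))
  gens <- c(gens, rep(3L, rbinom(1, 4, 0.6)))
  if (length(gens) == 0) gens <- 1L
  entries <- tibble::tibble(
    ancestor_id = paste0("a", seq_along(gens)),
    generation = gens,
    lineage = paste0("L", seq_along(gens)),
    age = runif(length(gens), 16, 65),
    weight = 0.5^gens
  )
  missing <- c(`1` = 1L - sum(gens == 1), `2` = 2L - sum(gens == 2),
               `3` = 4L - sum(gens == 3))
  structure(list(proband_id = "p", entries = entries,
                 missing_by_generation = missing),
            class = "ancestor_ages")
}

# cohort drawn straight from a logistic law: logit P(outcome) = a + b * wmama
direct_logit_cohort <- function(n, intercept, slope, wmama_mean = 33,
                                wmama_sd = 2.7) {
  w <- rnorm(n, wmama_mean, wmama_sd)
  tibble::tibble(
    outcome = rbinom(n, 1, plogis(intercept + slope * w)),
    wmama = w
  )
}

fixture_path <- function() {
  system.file("extdata", "synthetic_pedigree_4gen.tsv", package = "wmama")
}
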