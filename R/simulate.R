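# Forward-time generator of monogamous multi-generation pedigrees.
#
# Mutational model: a child receives de novo deleterious point mutations at a
# Poisson rate that grows linearly with the father's age (about 20 extra
# point mutations per decade of paternal age, of which a fraction f_del are
# deleterious), a small age-independent maternal de novo contribution, and a
# Mendelian half of each parent's own deleterious count (binomial thinning
# with p = 0.5 per meiosis). Each deleterious mutation multiplies the
# probability of surviving to age 15 by (1 - hs); non-survivors never marry
# or reproduce, so selection purges load each generation.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_population()].
#' Defaults describe a pre-industrial, high-mortality, strictly monogamous
#' population: paternal ages concentrated near 30--36 years, roughly 40% of
#' children dying before age 15, and a paternal-age-dependent de novo
#' mutation count rising by ~20 point mutations per decade.
#'
#' @param n_founder_couples Number of mutation-free founder couples.
#' @param n_generations Total generations including founders; at least 4 so
#'   that final-generation probands have in-pedigree great-grandfathers.
#' @param paternal_age_mean,paternal_age_sd,paternal_age_range Truncated
#'   normal law for a father's age at each birth (years).
#' @param maternal_age_mean,maternal_age_sd,maternal_age_range Truncated
#'   normal law used as the wives' fertile-age window (years).
#' @param lambda_ref Expected de novo point mutations at paternal age 30.
#' @param beta Extra point mutations per year of paternal age.
#' @param f_del Fraction of point mutations that are deleterious.
#' @param hs Multiplicative survival penalty per deleterious mutation.
#' @param s0 Baseline probability of surviving to 15 with zero mutations.
#' @param maternal_denovo_point Age-independent maternal de novo point
#'   mutations (deleterious mean is `maternal_denovo_point * f_del`).
#' @param marriage_base Baseline probability that a survivor marries.
#' @param female_marriage_wmama_slope Logit-scale penalty per year of WMAMA
#'   on female marriage probability (0 disables the mechanism).
#' @param covariate_effects Logit-scale nuisance effects on survival:
#'   `parish_sd` (between-parish intercept SD), `class` (named vector for
#'   rich/middle/poor), `twin`, `maternal_age` (per year, centred at
#'   `maternal_age_mean`).
#' @param n_parishes Number of parishes; couples marry within parish.
#' @param mean_children Poisson mean number of births per couple.
#' @param twin_prob Probability that a birth is a twin birth.
#' @param emigration_prob Probability that a survivor emigrates (and so
#'   leaves the marriage pool).
#' @param start_year Approximate founder birth year.
#' @param seed Master RNG seed; the whole run is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_founder_couples = 60,
                       n_generations = 5,
                       paternal_age_mean = 33, paternal_age_sd = 6,
                       paternal_age_range = c(18, 60),
                       maternal_age_mean = 29, maternal_age_sd = 5,
                       maternal_age_range = c(16, 45),
                       lambda_ref = 60, beta = 2, f_del = 0.05,
                       hs = 0.04, s0 = 0.62,
                       maternal_denovo_point = 15,
                       marriage_base = 0.85,
                       female_marriage_wmama_slope = 0,
                       covariate_effects = list(
                         parish_sd = 0.3,
                         class = c(rich = 0, middle = -0.05, poor = -0.3),
                         twin = -1.2,
                         maternal_age = -0.01
                       ),
                       n_parishes = 7,
                       mean_children = 7,
                       twin_prob = 0.015,
                       emigration_prob = 0.02,
                       start_year = 1700,
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(f_del = f_del, hs = hs, s0 = s0, marriage_base = marriage_base,
             twin_prob = twin_prob, emigration_prob = emigration_prob)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    abort(paste0("Probabilities out of [0, 1]: ",
                 paste(names(probs)[bad], collapse = ", ")))
  }
  if (n_generations < 2) abort("`n_generations` must be at least 2.")
  if (lambda_ref + beta * (paternal_age_range[1] - 30) < 0) {
    abort("De novo mean is negative at the youngest paternal age; lower `beta` or raise `lambda_ref`.")
  }
  cls <- covariate_effects$class
  if (is.null(names(cls)) || !setequal(names(cls), SOCIAL_CLASSES)) {
    abort("`covariate_effects$class` must be named rich/middle/poor.")
  }
  structure(cfg, class = "sim_config")
}

# inverse-CDF truncated normal draw (deterministic under the global RNG)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  p <- runif(n, stats::pnorm(lower, mean, sd), stats::pnorm(upper, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Draw paternal-age-dependent de novo deleterious mutation counts
#'
#' Poisson with mean `(lambda_ref + beta * (father_age - 30)) * f_del`.
#' Deterministic given the global RNG state (use `set.seed()`).
#'
#' @param father_age Vector of paternal ages (years).
#' @param config A [sim_config()].
#' @param n Number of draws per age (draws are vectorised over `father_age`
#'   when `n` is 1).
#' @return Integer vector of deleterious de novo counts.
#' @export
sample_de_novo_count <- function(father_age, config = sim_config(), n = 1) {
  mean_k <- (config$lambda_ref + config$beta * (father_age - 30)) * config$f_del
  if (any(mean_k < 0)) {
    abort("Negative de novo mean: paternal age outside the configured support.")
  }
  if (n == 1) rpois(length(father_age), mean_k) else rpois(n, mean_k)
}

#' Mendelian transmission of mutation counts
#'
#' Each of a parent's deleterious mutations is passed to the child
#' independently with probability 1/2 (binomial thinning per meiosis).
#'
#' @param parent_count Non-negative integer vector of parental counts.
#' @return Integer vector of transmitted counts.
#' @export
transmit_mutations <- function(parent_count) {
  if (any(parent_count < 0)) abort("`parent_count` must be non-negative.")
  rbinom(length(parent_count), parent_count, 0.5)
}

#' Survival-to-15 probability under mutational and covariate load
#'
#' `s0 * (1 - hs)^k`, shifted on the logit scale by any covariate
#' contribution and clamped to the unit interval.
#'
#' @param k_total_del Total deleterious mutation count.
#' @param config A [sim_config()].
#' @param covariate_logit Logit-scale covariate contribution (default 0).
#' @return Survival probability vector.
#' @export
survival_probability <- function(k_total_del, config = sim_config(),
                                 covariate_logit = 0) {
  if (any(k_total_del < 0)) abort("`k_total_del` must be non-negative.")
  base <- config$s0 * (1 - config$hs)^k_total_del
  if (all(covariate_logit == 0)) return(base)
  base <- pmin(pmax(base, 1e-12), 1 - 1e-12)
  p <- plogis(qlogis(base) + covariate_logit)
  if (any(p < 0 | p > 1)) {
    warn("Survival probability clamped to [0, 1].")
    p <- pmin(pmax(p, 0), 1)
  }
  p
}

#' Simulate a multi-generation pedigree with mutational selection
#'
#' Founder couples start mutation-free. Each generation, couples produce a
#' Poisson number of births at paternal ages drawn from the configured law
#' (births are kept only when the mother is within her fertile window and
#' both parents are alive); children accumulate inherited and de novo
#' deleterious mutations, survive to 15 with probability
#' [survival_probability()], and surviving non-emigrants marry monogamously
#' within parish to form the next generation's couples. Wives take their
#' husband's social class. The run is fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `simulated_cohort`: list with `pedigree` (a [as_pedigree()]
#'   tibble) and `truth` (per-individual generative truth: mutation counts,
#'   survival, marriage, parish, class, twin status, parental ages and the
#'   individual's true WMAMA where defined).
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  parishes <- paste0("parish", seq_len(cfg$n_parishes))
  parish_eff <- setNames(rnorm(cfg$n_parishes, 0, cfg$covariate_effects$parish_sd),
                         parishes)
  class_eff <- cfg$covariate_effects$class

  n0 <- cfg$n_founder_couples
  founders <- tibble(
    id = c(paste0("g1_m", seq_len(n0)), paste0("g1_f", seq_len(n0))),
    sex = rep(c("male", "female"), each = n0),
    father_id = NA_character_, mother_id = NA_character_,
    birth_year = round(c(rnorm(n0, cfg$start_year, 3),
                         rnorm(n0, cfg$start_year + 4, 3)), 2),
    parish = rep(sample(parishes, n0, replace = TRUE), 2),
    social_class = rep(sample(SOCIAL_CLASSES, n0, replace = TRUE,
                              prob = c(0.3, 0.4, 0.3)), 2),
    twin = FALSE, first_born = NA,
    married = TRUE,
    emigration_year = NA_real_,
    generation = 1L,
    k = 0L, k_denovo = 0L, k_inherited = 0L,
    survived15 = TRUE,
    father_age = NA_real_, mother_age = NA_real_,
    # incremental WMAMA state: generation-wise sums of male-ancestor ages
    a1 = NA_real_, a2_sum = 0, a2_n = 0L, a3_sum = 0, a3_n = 0L,
    n_children = 0L
  )
  death_age <- rtruncnorm(2 * n0, 50, 15, 16, 90)
  founders$death_year <- round(founders$birth_year + death_age, 2)
  founders$marriage_year <- round(pmax(founders$birth_year[seq_len(n0)],
                                       founders$birth_year[n0 + seq_len(n0)]) +
                                    runif(n0, 19, 24), 2)[rep(seq_len(n0), 2)]

  couples <- tibble(
    husband = founders$id[seq_len(n0)],
    wife = founders$id[n0 + seq_len(n0)]
  )
  all_gen <- list(founders)
  lookup <- founders

  for (g in seq_len(cfg$n_generations - 1) + 1) {
    if (nrow(couples) == 0) {
      abort(paste0("Population went extinct: no couples at generation ", g, "."))
    }
    h <- lookup[match(couples$husband, lookup$id), ]
    w <- lookup[match(couples$wife, lookup$id), ]
    n_births <- rpois(nrow(couples), cfg$mean_children)
    cidx <- rep(seq_len(nrow(couples)), n_births)
    if (length(cidx) == 0) {
      abort(paste0("Population went extinct: no births at generation ", g, "."))
    }
    f_age <- rtruncnorm(length(cidx), cfg$paternal_age_mean,
                        cfg$paternal_age_sd,
                        cfg$paternal_age_range[1], cfg$paternal_age_range[2])
    birth <- round(h$birth_year[cidx] + f_age, 2)
    m_age <- birth - w$birth_year[cidx]
    keep <- m_age >= cfg$maternal_age_range[1] &
      m_age <= cfg$maternal_age_range[2] &
      birth >= h$marriage_year[cidx] &
      birth <= h$death_year[cidx] & birth <= w$death_year[cidx]
    cidx <- cidx[keep]; f_age <- f_age[keep]
    birth <- birth[keep]; m_age <- m_age[keep]
    if (length(cidx) == 0) {
      abort(paste0("Population went extinct: no viable births at generation ",
                   g, "."))
    }
    # twin births duplicate the birth event
    is_twin_birth <- runif(length(cidx)) < cfg$twin_prob
    dup <- c(seq_along(cidx), which(is_twin_birth))
    ord <- order(cidx[dup], birth[dup])
    cidx <- cidx[dup][ord]; f_age <- round(f_age[dup][ord], 2)
    birth <- birth[dup][ord]; m_age <- round(m_age[dup][ord], 2)
    twin <- (duplicated(paste(cidx, birth)) |
               duplicated(paste(cidx, birth), fromLast = TRUE))
    n_kid <- length(cidx)

    hk <- h$k[cidx]; wk <- w$k[cidx]
    k_inh <- transmit_mutations(hk) + transmit_mutations(wk)
    k_den <- sample_de_novo_count(f_age, cfg) +
      rpois(n_kid, cfg$maternal_denovo_point * cfg$f_del)
    k_tot <- k_inh + k_den

    parish <- h$parish[cidx]
    s_class <- h$social_class[cidx]
    cov_logit <- parish_eff[parish] + class_eff[s_class] +
      cfg$covariate_effects$twin * twin +
      cfg$covariate_effects$maternal_age * (m_age - cfg$maternal_age_mean)
    p_surv <- survival_probability(k_tot, cfg, cov_logit)
    surv <- runif(n_kid) < p_surv
    death_year <- round(ifelse(surv,
                               birth + rtruncnorm(n_kid, 50, 15, 16, 90),
                               birth + runif(n_kid, 0, 15)), 2)
    emigrates <- surv & runif(n_kid) < cfg$emigration_prob
    emigration_year <- ifelse(emigrates, round(birth + runif(n_kid, 5, 40), 2),
                              NA_real_)

    first_born <- !duplicated(cidx)
    kids <- tibble(
      id = paste0("g", g, "_", seq_len(n_kid)),
      sex = ifelse(runif(n_kid) < 0.5, "male", "female"),
      father_id = h$id[cidx], mother_id = w$id[cidx],
      birth_year = birth,
      parish = parish, social_class = s_class,
      twin = twin, first_born = first_born,
      married = FALSE,
      emigration_year = emigration_year,
      generation = as.integer(g),
      k = k_tot, k_denovo = k_den, k_inherited = k_inh,
      survived15 = surv,
      father_age = f_age, mother_age = m_age,
      a1 = f_age,
      a2_sum = ifelse(is.na(h$a1[cidx]), 0, h$a1[cidx]) +
        ifelse(is.na(w$a1[cidx]), 0, w$a1[cidx]),
      a2_n = (!is.na(h$a1[cidx])) + (!is.na(w$a1[cidx])),
      a3_sum = h$a2_sum[cidx] + w$a2_sum[cidx],
      a3_n = h$a2_n[cidx] + w$a2_n[cidx],
      death_year = death_year,
      marriage_year = NA_real_,
      n_children = 0L
    )

    # record completed fertility on the parents
    per_couple <- tabulate(cidx, nbins = nrow(couples))
    kid_counts <- setNames(per_couple, couples$husband)
    kid_counts_w <- setNames(per_couple, couples$wife)
    for (tbl_i in seq_along(all_gen)) {
      hit_h <- all_gen[[tbl_i]]$id %in% names(kid_counts)
      hit_w <- all_gen[[tbl_i]]$id %in% names(kid_counts_w)
      if (any(hit_h)) {
        all_gen[[tbl_i]]$n_children[hit_h] <-
          kid_counts[all_gen[[tbl_i]]$id[hit_h]]
      }
      if (any(hit_w)) {
        all_gen[[tbl_i]]$n_children[hit_w] <-
          kid_counts_w[all_gen[[tbl_i]]$id[hit_w]]
      }
    }

    # marriage and monogamous within-parish pairing; the final generation is
    # paired too (so probands carry marriage and fertility outcomes) but its
    # children are recorded only as counts, not as pedigree rows
    wm <- with(kids, 0.5 * a1 + 0.25 * a2_sum + 0.125 * a3_sum) /
      with(kids, 0.5 + 0.25 * a2_n + 0.125 * a3_n)
    logit_marry <- qlogis(cfg$marriage_base) +
      ifelse(kids$sex == "female" & !is.na(wm),
             cfg$female_marriage_wmama_slope * (wm - cfg$paternal_age_mean), 0)
    willing <- kids$survived15 & !emigrates & runif(n_kid) < plogis(logit_marry)
    new_couples <- list()
    for (p in parishes) {
      males <- which(willing & kids$sex == "male" & kids$parish == p)
      females <- which(willing & kids$sex == "female" & kids$parish == p)
      males <- males[sample.int(length(males))]
      females <- females[sample.int(length(females))]
      n_pair <- min(length(males), length(females))
      if (n_pair == 0) next
      mi <- males[seq_len(n_pair)]; fi <- females[seq_len(n_pair)]
      myr <- round(pmax(kids$birth_year[mi], kids$birth_year[fi]) +
                     runif(n_pair, 19, 24), 2)
      ok <- myr <= kids$death_year[mi] & myr <= kids$death_year[fi]
      mi <- mi[ok]; fi <- fi[ok]; myr <- myr[ok]
      if (length(mi) == 0) next
      kids$married[c(mi, fi)] <- TRUE
      kids$marriage_year[c(mi, fi)] <- rep(myr, 2)
      kids$social_class[fi] <- kids$social_class[mi]
      new_couples[[p]] <- tibble(husband = kids$id[mi], wife = kids$id[fi])
    }
    couples <- bind_rows(new_couples)
    if (g == cfg$n_generations && nrow(couples) > 0) {
      final_births <- rpois(nrow(couples), cfg$mean_children)
      kids$n_children[match(couples$husband, kids$id)] <- final_births
      kids$n_children[match(couples$wife, kids$id)] <- final_births
    }
    all_gen[[length(all_gen) + 1]] <- kids
    lookup <- kids
  }

  everyone <- bind_rows(all_gen)
  wm_all <- with(everyone, 0.5 * a1 + 0.25 * a2_sum + 0.125 * a3_sum) /
    with(everyone, 0.5 + 0.25 * a2_n + 0.125 * a3_n)
  pedigree <- as_pedigree(everyone[PEDIGREE_COLUMNS])
  truth <- everyone |>
    transmute(
      id = .data$id,
      generation = .data$generation,
      k_denovo_del = .data$k_denovo,
      k_inherited_del = .data$k_inherited,
      k_total_del = .data$k,
      survived15 = .data$survived15,
      married = .data$married,
      n_children = .data$n_children,
      parish = .data$parish,
      social_class = .data$social_class,
      twin = .data$twin,
      father_age = .data$father_age,
      maternal_age = .data$mother_age,
      wmama_true = wm_all
    )
  structure(
    list(pedigree = pedigree, truth = truth, config = cfg,
         parish_effects = parish_eff),
    class = "simulated_cohort"
  )
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort>", nrow(x$pedigree), "individuals over",
      x$config$n_generations, "generations; probands:",
      sum(x$truth$generation == x$config$n_generations), "\n")
  invisible(x)
}

#' Final-generation probands of a simulated cohort
#'
#' @param sim A `simulated_cohort`.
#' @return Character vector of proband ids (the last generation).
#' @export
proband_ids <- function(sim) {
  stopifnot(inherits(sim, "simulated_cohort"))
  sim$truth$id[sim$truth$generation == sim$config$n_generations]
}
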