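test_that("model log-likelihoods match a brute-force evaluation", {
  set.seed(8)
  df <- tibble::tibble(
    wmama = rnorm(20, 33, 3),
    outcome = rbinom(20, 1, 0.6)
  )
  fit <- fit_model(df, model_spec("survival15", covariates = character(),
                                  cluster = NULL))
  eta <- cbind(1, df$wmama) %*% coef(fit$fit)
  p <- plogis(eta)
  ll <- sum(df$outcome * log(p) + (1 - df$outcome) * log(1 - p))
  expect_equal(fit$model_loglik, ll, tolerance = 1e-8)

  dfp <- tibble::tibble(wmama = rnorm(20, 33, 3))
  dfp$outcome <- rpois(20, exp(0.5 + 0.02 * dfp$wmama))
  fitp <- fit_model(dfp, model_spec("lbs", covariates = character(),
                                    cluster = NULL))
  lam <- exp(cbind(1, dfp$wmama) %*% coef(fitp$fit))
  llp <- sum(stats::dpois(dfp$outcome, lam, log = TRUE))
  expect_equal(fitp$model_loglik, llp, tolerance = 1e-8)
})

test_that("degenerate inputs raise informative fitting errors", {
  expect_error(model_spec("immortality"), "Unknown outcome")
  one <- tibble::tibble(outcome = 1L, wmama = 33)
  expect_error(fit_model(one, model_spec("survival15",
                                         covariates = character(),
                                         cluster = NULL)),
               "Insufficient data")
  set.seed(10)
  dup <- tibble::tibble(wmama = rnorm(60, 33, 3),
                        outcome = rbinom(60, 1, 0.5))
  dup$wm_copy <- dup$wmama
  expect_error(fit_model(dup, model_spec("survival15",
                                         covariates = "wm_copy",
                                         cluster = NULL)),
               "collinear.*wm_copy")
  expect_error(fit_model(dplyr::mutate(dup, wmama = NA_real_),
                         model_spec("survival15", covariates = character(),
                                    cluster = NULL)),
               "missing values")
})

test_that("factor levels with constant binomial outcomes are dropped", {
  set.seed(11)
  df <- tibble::tibble(
    wmama = rnorm(300, 33, 3),
    parish = sample(c("a", "b", "c"), 300, replace = TRUE),
    outcome = rbinom(300, 1, 0.5)
  )
  df$outcome[df$parish == "c"] <- 1L
  expect_warning(
    fit <- fit_model(df, model_spec("survival15", covariates = "parish",
                                    cluster = NULL)),
    "degenerate parish"
  )
  expect_false(any(grepl("parishc", fit$coefficients$term)))
  expect_equal(fit$n_rows, sum(df$parish != "c"))
})

test_that("effect translation matches the inverse logit by hand", {
  # synthetic fit with known coefficients: intercept 0.5, slope -0.036
  set.seed(12)
  big <- direct_logit_cohort(60000, intercept = 0.5, slope = -0.036)
  fit <- fit_model(big, model_spec("survival15", covariates = character(),
                                   cluster = NULL))
  tr <- translate_effect(fit)
  # hand values at the true coefficients
  p30 <- plogis(0.5 - 0.036 * 30)   # 0.3589
  p40 <- plogis(0.5 - 0.036 * 40)   # 0.2807
  expect_equal(tr$p_ref, p30, tolerance = 0.03)
  expect_equal(tr$p_cmp, p40, tolerance = 0.03)
  expect_equal(tr$relative_decline, (p30 - p40) / p30, tolerance = 0.12)
  expect_equal(round((p30 - p40) / p30, 3), 0.217)

  # exact internal consistency, whatever was estimated
  expect_equal(tr$absolute_decline, tr$p_ref - tr$p_cmp)
  expect_equal(tr$relative_decline * tr$p_ref, tr$absolute_decline)
  expect_true(tr$relative_decline_low <= tr$relative_decline)
  expect_true(tr$relative_decline_high >= tr$relative_decline)

  # monotonicity of predictions under a negative coefficient
  eta <- predict(fit$fit,
                 newdata = tibble::tibble(wmama = seq(25, 45, by = 2.5)),
                 type = "response")
  expect_true(all(diff(eta) < 0))

  # zero slope translates to zero decline
  flat <- fit
  flat$fit$coefficients["wmama"] <- 0
  flat$coefficients$estimate[flat$coefficients$term == "wmama"] <- 0
  tr0 <- translate_effect(flat)
  expect_equal(tr0$relative_decline, 0)
  expect_error(translate_effect(fitp <- fit_model(
    tibble::tibble(outcome = rpois(50, 3), wmama = rnorm(50, 33, 3)),
    model_spec("lbs", covariates = character(), cluster = NULL)
  )), "binomial")
})

test_that("permutation inference is deterministic, bounded and honest", {
  set.seed(14)
  coh <- tibble::tibble(
    wmama = rnorm(250, 33, 3),
    parish = sample(c("a", "b"), 250, replace = TRUE)
  )
  # maximal signal: outcome is a deterministic function of the exposure
  coh$outcome <- as.integer(round(coh$wmama))
  spec <- model_spec("lbs", covariates = character(), cluster = NULL)
  pt <- permutation_test(coh, spec, n_permutations = 99, seed = 5)
  expect_equal(pt$permutation_p, 1 / 100)
  pt2 <- permutation_test(coh, spec, n_permutations = 99, seed = 5)
  expect_identical(pt$permutation_p, pt2$permutation_p)
  expect_error(permutation_test(coh, spec, n_permutations = 10), "at least 99")

  # independent exposure: p is not systematically small
  set.seed(15)
  coh$outcome <- rpois(250, 3)
  pn <- permutation_test(coh, spec, n_permutations = 199, seed = 6)
  expect_gt(pn$permutation_p, 0.01)
})

test_that("backward pruning removes only null covariates, never the exposure", {
  set.seed(16)
  n <- 2500
  df <- tibble::tibble(
    wmama = rnorm(n, 33, 3),
    parish = sample(c("a", "b"), n, replace = TRUE),
    twin = runif(n) < 0.05,
    maternal_age = rnorm(n, 29, 5)
  )
  eta <- 1.2 - 0.05 * df$wmama + 1.0 * (df$parish == "b") # twin, maternal null
  df$outcome <- rbinom(n, 1, plogis(eta))
  spec <- model_spec("survival15",
                     covariates = c("parish", "twin", "maternal_age"),
                     cluster = NULL)
  pruned <- backward_prune(df, spec)
  expect_true("parish" %in% pruned$covariates)
  expect_false("twin" %in% pruned$covariates)
  expect_false("maternal_age" %in% pruned$covariates)
  expect_equal(pruned$exposure, "wmama")

  # all effects real: nothing is dropped
  eta2 <- 1.2 - 0.05 * df$wmama + 1.0 * (df$parish == "b") - 1.5 * df$twin +
    0.09 * df$maternal_age
  df2 <- dplyr::mutate(df, outcome = rbinom(n, 1, plogis(eta2)))
  pruned2 <- backward_prune(df2, spec)
  expect_setequal(pruned2$covariates, c("parish", "twin", "maternal_age"))

  # exposure-only specification is returned unchanged
  bare <- model_spec("survival15", covariates = character(), cluster = NULL)
  expect_equal(backward_prune(df, bare)$covariates, character(0))
})

test_that("the person-year hazard model recovers a known hazard ratio", {
  set.seed(18)
  n <- 6000
  w <- rnorm(n, 33, 3)
  h0 <- 0.035
  hr_per_year <- 1.03
  p_death <- plogis(qlogis(h0) + log(hr_per_year) * (w - 33))
  # draw age at death under a constant per-year hazard up to 15
  u <- runif(n)
  yrs_to_death <- ceiling(log(1 - u) / log(1 - p_death))
  died <- yrs_to_death <= 15
  df <- tibble::tibble(
    proband_id = as.character(seq_len(n)),
    wmama = w,
    birth_year = 1800,
    death_year = 1800 + ifelse(died, yrs_to_death - 0.5, 70),
    outcome = as.integer(!died)
  )
  fit <- discrete_time_hazard(df, model_spec("hazard",
                                             covariates = character(),
                                             cluster = NULL))
  est <- fit$coefficients[fit$coefficients$term == "wmama", ]
  expect_true(est$conf_low <= log(hr_per_year) &&
                log(hr_per_year) <= est$conf_high)
  expect_equal(fit$hazard_ratio, exp(est$estimate))

  no_deaths <- dplyr::mutate(df, death_year = 1900)
  expect_error(discrete_time_hazard(no_deaths, model_spec("hazard",
                                                          covariates = character(),
                                                          cluster = NULL)),
               "No deaths")
})

test_that("AIC screening prefers the generative interaction structure", {
  set.seed(19)
  n <- 3000
  base_df <- tibble::tibble(
    wmama = rnorm(n, 33, 3),
    sex = sample(c("female", "male"), n, replace = TRUE)
  )
  # no interaction in truth
  y0 <- rbinom(n, 1, plogis(1.5 - 0.05 * base_df$wmama))
  spec <- model_spec("survival15", covariates = "sex", cluster = NULL)
  cmp0 <- compare_models(dplyr::mutate(base_df, outcome = y0), spec,
                         interactions = "sex")
  expect_equal(cmp0$model[1], "base")

  # strong exposure-by-sex interaction in truth
  slope <- ifelse(base_df$sex == "female", -0.12, 0)
  y1 <- rbinom(n, 1, plogis(2 + slope * base_df$wmama))
  cmp1 <- compare_models(dplyr::mutate(base_df, outcome = y1), spec,
                         interactions = "sex")
  expect_equal(cmp1$model[1], "exposure_x_sex")
})

test_that("marriage analyses stratify by sex with independent fits", {
  sim <- simulate_population(sim_config(n_founder_couples = 250, seed = 23))
  coh <- build_cohort(sim$pedigree, "marriage")
  males <- dplyr::filter(coh, sex == "male")
  females <- dplyr::filter(coh, sex == "female")
  expect_equal(nrow(males) + nrow(females), nrow(coh))
  spec <- model_spec("marriage", covariates = c("parish", "social_class"))
  fm <- fit_model(males, spec)
  ff <- fit_model(females, spec)
  expect_equal(fm$n_rows, nrow(males))
  expect_equal(ff$n_rows, nrow(females))
  expect_false(identical(fm$coefficients$estimate, ff$coefficients$estimate))
})

test_that("tidy and glance expose the fit in broom style", {
  set.seed(25)
  df <- direct_logit_cohort(500, intercept = 1, slope = -0.04)
  fit <- fit_model(df, model_spec("survival15", covariates = character(),
                                  cluster = NULL))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "conf_low",
                    "conf_high") %in% names(td)))
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
  gl <- glance(fit)
  expect_equal(gl$n, 500L)
  expect_equal(gl$family, "binomial")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(quartile_summary(df, "outcome")), "ggplot")
})
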