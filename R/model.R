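# Maximum-likelihood regressions of fitness outcomes on the ancestral-age
# exposure. Binomial-logit for survival to 15 and marriage, Poisson-log for
# longevity and lifetime breeding success; standard errors are made robust
# to within-family correlation by clustering on maternal identity.

#' Specify a fitness regression model
#'
#' @param outcome One of `"survival15"`, `"longevity"`, `"marriage"`,
#'   `"lbs"`, `"hazard"`. Fixes the family: binomial-logit for `survival15`,
#'   `marriage` and `hazard`; Poisson-log for `longevity` and `lbs`.
#' @param exposure Exposure column: `"wmama"` (default),
#'   `"wmama_excl_father"` or `"father_age"`.
#' @param covariates Fixed-effect columns. `"birth_year_bin"` expands
#'   `birth_year` into 25-year period bins; `"maternal_age_sq"` adds a
#'   quadratic maternal-age term.
#' @param cluster Column for cluster-robust standard errors (`NULL` for
#'   model-based errors).
#' @param interactions Covariates whose interaction with the exposure is
#'   added to the model.
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome,
                       exposure = "wmama",
                       covariates = c("parish", "social_class", "twin",
                                      "first_born", "maternal_age", "sex"),
                       cluster = "mother_id",
                       interactions = character()) {
  if (!outcome %in% c(OUTCOMES, "hazard")) {
    abort(paste0("Unknown outcome `", outcome, "`."))
  }
  family <- if (outcome %in% c("survival15", "marriage", "hazard")) {
    "binomial"
  } else {
    "poisson"
  }
  structure(
    list(outcome = outcome, family = family, exposure = exposure,
         covariates = covariates, cluster = cluster,
         interactions = interactions),
    class = "model_spec"
  )
}

# Model frame with the field's reference levels: rich social class, first
# parish, singleton, female, earliest birth-year bin.
prepare_model_frame <- function(cohort, spec) {
  cols <- unique(c("outcome", spec$exposure,
                   setdiff(spec$covariates,
                           c("birth_year_bin", "maternal_age_sq")),
                   if ("birth_year_bin" %in% spec$covariates) "birth_year",
                   if ("maternal_age_sq" %in% spec$covariates) "maternal_age",
                   spec$cluster))
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(cohort)[cols]
  if (any(!complete.cases(df))) {
    abort("Cohort has missing values in model columns; filter before fitting.")
  }
  if ("social_class" %in% names(df)) {
    df$social_class <- factor(df$social_class, levels = SOCIAL_CLASSES)
    df$social_class <- droplevels(df$social_class)
  }
  if ("parish" %in% names(df)) df$parish <- factor(df$parish)
  if ("sex" %in% names(df)) df$sex <- factor(df$sex, levels = c("female", "male"))
  if ("birth_year_bin" %in% spec$covariates) {
    breaks <- seq(25 * floor(min(df$birth_year) / 25),
                  25 * ceiling(max(df$birth_year) / 25), by = 25)
    df$birth_year_bin <- droplevels(cut(df$birth_year, breaks,
                                        include.lowest = TRUE, right = TRUE))
  }
  if ("maternal_age_sq" %in% spec$covariates) {
    df$maternal_age_sq <- df$maternal_age^2
  }
  df
}

# Drop factor levels in which a binomial outcome never varies (they would be
# fitted to +/- infinity, as with a parish where everyone marries).
drop_degenerate_levels <- function(df, spec) {
  if (spec$family != "binomial") return(df)
  for (col in intersect(c("parish", "social_class", "birth_year_bin"),
                        names(df))) {
    if (!is.factor(df[[col]]) || nlevels(df[[col]]) < 2) next
    var_by <- tapply(df$outcome, df[[col]], function(y) length(unique(y)))
    bad <- names(var_by)[!is.na(var_by) & var_by == 1]
    if (length(bad) > 0 && length(bad) < nlevels(df[[col]])) {
      warn(paste0("Dropping degenerate ", col, " level(s) with constant ",
                  "outcome: ", paste(bad, collapse = ", ")))
      df <- df[!df[[col]] %in% bad, ]
      df[[col]] <- droplevels(df[[col]])
    }
  }
  df
}

build_formula <- function(spec) {
  covs <- spec$covariates
  if ("maternal_age_sq" %in% covs) {
    covs <- union(covs, "maternal_age")
  }
  rhs <- c(spec$exposure, covs,
           if (length(spec$interactions) > 0) {
             paste0(spec$exposure, ":", spec$interactions)
           })
  stats::as.formula(paste("outcome ~", paste(rhs, collapse = " + ")))
}

#' Fit a fitness regression
#'
#' Fits the specified generalized linear model by maximum likelihood and
#' computes cluster-robust standard errors and Wald 95% confidence intervals
#' for every coefficient. Degenerate factor levels (a category in which a
#' binomial outcome never varies) are dropped with a warning; rank-deficient
#' designs and non-convergence raise errors naming the offending terms.
#'
#' @param cohort A cohort from [build_cohort()] (or any data frame with the
#'   spec's columns plus `outcome`).
#' @param spec A [model_spec()].
#' @return A `wmama_fit` object; see [tidy()] and [glance()] methods, and
#'   [translate_effect()] for converting the exposure coefficient into
#'   predicted outcome declines.
#' @export
fit_model <- function(cohort, spec) {
  stopifnot(inherits(spec, "model_spec"))
  df <- prepare_model_frame(cohort, spec)
  df <- drop_degenerate_levels(df, spec)
  fml <- build_formula(spec)
  n_terms <- length(attr(stats::terms(fml), "term.labels"))
  if (nrow(df) <= n_terms + 1) {
    abort(paste0("Insufficient data: ", nrow(df), " row(s) for ", n_terms,
                 " model term(s)."))
  }
  fam <- if (spec$family == "binomial") binomial("logit") else poisson("log")
  fit <- glm(fml, family = fam, data = df)
  if (!fit$converged) {
    abort(paste0("Model did not converge after ", fit$iter, " iterations; ",
                 "deviance ", signif(fit$deviance, 6), "."))
  }
  if (anyNA(coef(fit))) {
    abort(paste0("Rank-deficient design; collinear term(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  if (spec$family == "binomial" && any(abs(coef(fit)) > 15)) {
    warn("Very large logit coefficient(s); possible separation.")
  }
  vc <- if (!is.null(spec$cluster)) {
    sandwich::vcovCL(fit, cluster = df[[spec$cluster]])
  } else {
    stats::vcov(fit)
  }
  est <- coef(fit)
  se <- sqrt(diag(vc))
  z <- qnorm(0.975)
  coefs <- tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(est / se),
    p_value = 2 * stats::pnorm(-abs(unname(est / se))),
    conf_low = unname(est - z * se),
    conf_high = unname(est + z * se)
  )
  structure(
    list(
      fit = fit, spec = spec, data = df, vcov = vc,
      coefficients = coefs,
      exposure_coefficient = unname(est[spec$exposure]),
      n_rows = nrow(df),
      model_loglik = as.numeric(logLik(fit)),
      aic = AIC(fit),
      permutation_p = NA_real_
    ),
    class = "wmama_fit"
  )
}

#' @export
print.wmama_fit <- function(x, ...) {
  cat("<wmama_fit>", x$spec$outcome, "~", x$spec$exposure, "+",
      length(x$spec$covariates), "covariate(s);",
      x$spec$family, "family; n =", x$n_rows, "\n")
  cat("  exposure coefficient:", signif(x$exposure_coefficient, 4),
      " AIC:", round(x$aic, 1), "\n")
  if (!is.na(x$permutation_p)) {
    cat("  permutation p:", x$permutation_p, "\n")
  }
  invisible(x)
}

# which covariates have at least one coefficient whose 95% CI excludes zero
covariate_significance <- function(fitted, covariates) {
  coefs <- fitted$coefficients
  vapply(covariates, function(cv) {
    hits <- startsWith(coefs$term, cv) &
      !startsWith(coefs$term, fitted$spec$exposure)
    any(coefs$conf_low[hits] > 0 | coefs$conf_high[hits] < 0)
  }, logical(1))
}

#' Backward pruning of non-significant covariates
#'
#' Iteratively removes fixed effects whose 95% confidence intervals (all
#' levels, for factors) cover zero, never touching the exposure. Maternal age
#' is retained regardless if it was significant in the model fitted before
#' the exposure entered, mirroring the convention of keeping possibly
#' confounding terms.
#'
#' @param cohort A cohort table.
#' @param spec Initial [model_spec()].
#' @return The pruned `model_spec`.
#' @export
backward_prune <- function(cohort, spec) {
  locked <- character()
  if ("maternal_age" %in% spec$covariates) {
    pre_spec <- spec
    pre_spec$exposure <- "maternal_age"
    pre_spec$covariates <- setdiff(spec$covariates, "maternal_age")
    pre <- fit_model(cohort, pre_spec)
    ma <- filter(pre$coefficients, .data$term == "maternal_age")
    if (nrow(ma) == 1 && (ma$conf_low > 0 || ma$conf_high < 0)) {
      locked <- "maternal_age"
    }
  }
  current <- spec
  repeat {
    if (length(current$covariates) == 0) break
    fitted <- fit_model(cohort, current)
    sig <- covariate_significance(fitted, current$covariates)
    droppable <- setdiff(names(sig)[!sig], locked)
    if (length(droppable) == 0) break
    # drop the weakest: smallest maximum |z| among its terms
    weakest <- droppable[which.min(vapply(droppable, function(cv) {
      hits <- startsWith(fitted$coefficients$term, cv)
      max(abs(fitted$coefficients$statistic[hits]))
    }, numeric(1)))]
    current$covariates <- setdiff(current$covariates, weakest)
  }
  current
}

#' Discrete-time hazard model of childhood mortality
#'
#' Expands each proband into one record per year of life up to death or
#' censoring at age 15 and fits a logistic regression of the yearly death
#' indicator on age-year, the exposure and covariates — a discrete-time
#' approximation to a proportional-hazards model whose exponentiated
#' exposure coefficient is a per-WMAMA-year hazard ratio.
#'
#' @param cohort A `survival15` cohort from [build_cohort()] (needs
#'   `death_year` and `birth_year`).
#' @param spec A [model_spec()]; outcome is forced to `"hazard"`.
#' @return A `wmama_fit` with an extra `hazard_ratio` element.
#' @export
discrete_time_hazard <- function(cohort, spec = model_spec("hazard")) {
  spec$outcome <- "hazard"
  spec$family <- "binomial"
  df <- as_tibble(cohort)
  age_at_death <- df$death_year - df$birth_year
  died <- !is.na(age_at_death) & age_at_death < 15
  if (!any(died)) abort("No deaths before 15; the hazard model is degenerate.")
  years_obs <- ifelse(died, floor(age_at_death) + 1, 15)
  long <- df[rep(seq_len(nrow(df)), years_obs), ]
  long$year <- unlist(lapply(years_obs, seq_len)) - 1L
  long$outcome <- 0L
  last <- cumsum(years_obs)
  long$outcome[last] <- as.integer(died)
  long$year_f <- factor(long$year)
  spec$covariates <- union(spec$covariates, "year_f")
  out <- fit_model(long, spec)
  out$hazard_ratio <- exp(out$exposure_coefficient)
  out
}
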