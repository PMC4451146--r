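# Permutation inference, effect translation to the probability scale, and
# AIC-based interaction screening.

#' Stratified permutation test for the exposure coefficient
#'
#' Refits the model with the exposure column permuted within parish strata
#' and reports `p = (1 + #{|coef_perm| >= |coef_obs|}) / (n_permutations + 1)`.
#' Permutations reuse the observed model matrix and `glm.fit`, so the test is
#' fast and exactly reproducible from `seed`.
#'
#' @param cohort A cohort table.
#' @param spec A [model_spec()].
#' @param n_permutations Number of permutations (at least 99).
#' @param seed RNG seed.
#' @return The observed `wmama_fit` with `permutation_p` filled in.
#' @export
permutation_test <- function(cohort, spec, n_permutations = 999, seed = 1) {
  if (n_permutations < 99) abort("Use at least 99 permutations.")
  observed <- fit_model(cohort, spec)
  df <- observed$data
  set.seed(seed)
  X <- stats::model.matrix(observed$fit)
  y <- observed$fit$y
  fam <- observed$fit$family
  expo_col <- which(colnames(X) == spec$exposure)
  if (length(expo_col) != 1) {
    abort(paste0("Exposure `", spec$exposure,
                 "` is not a single model-matrix column."))
  }
  strata <- if ("parish" %in% names(df)) as.character(df$parish) else
    rep("all", nrow(df))
  obs_coef <- observed$exposure_coefficient
  idx_by_stratum <- split(seq_len(nrow(X)), strata)
  perm_coefs <- vapply(seq_len(n_permutations), function(b) {
    perm <- integer(nrow(X))
    for (s in idx_by_stratum) perm[s] <- s[sample.int(length(s))]
    Xb <- X
    Xb[, expo_col] <- X[perm, expo_col]
    fit_b <- suppressWarnings(
      stats::glm.fit(Xb, y, family = fam)
    )
    fit_b$coefficients[expo_col]
  }, numeric(1))
  observed$permutation_p <-
    (1 + sum(abs(perm_coefs) >= abs(obs_coef))) / (n_permutations + 1)
  observed$permutation_coefs <- perm_coefs
  observed
}

#' Translate an exposure coefficient into outcome declines
#'
#' For a binomial fit, predicts the outcome probability at two exposure
#' values (ancestral ages 30 and 40 by default) with every other covariate
#' held at a reference profile — factors at their reference level, logicals
#' FALSE, numeric covariates at their cohort mean — and reports the absolute
#' and relative decline between them. An interval for the relative decline
#' is obtained by sliding the exposure coefficient across its own 95%
#' confidence bounds (the decline is monotone in the coefficient, other
#' coefficients held fixed).
#'
#' @param fit A binomial `wmama_fit`.
#' @param reference,comparison Exposure values to compare (default 30, 40).
#' @param covariate_profile Named list overriding profile values.
#' @return An `effect_translation` one-row tibble: `reference`, `comparison`,
#'   `p_ref`, `p_cmp`, `absolute_decline`, `relative_decline`,
#'   `relative_decline_low`, `relative_decline_high`.
#' @export
translate_effect <- function(fit, reference = 30, comparison = 40,
                             covariate_profile = NULL) {
  stopifnot(inherits(fit, "wmama_fit"))
  if (fit$spec$family != "binomial") {
    abort("Effect translation to probabilities needs a binomial fit.")
  }
  expo <- fit$spec$exposure
  if (!expo %in% names(coef(fit$fit))) {
    abort(paste0("Exposure `", expo, "` is absent from the fitted model."))
  }
  df <- fit$data
  profile <- lapply(df[setdiff(names(df), c("outcome", expo))], function(col) {
    if (is.factor(col)) factor(levels(col)[1], levels = levels(col))
    else if (is.logical(col)) FALSE
    else if (is.numeric(col)) mean(col)
    else sort(unique(col))[1]
  })
  for (nm in names(covariate_profile)) profile[[nm]] <- covariate_profile[[nm]]
  newdata <- tibble(!!expo := c(reference, comparison))
  for (nm in names(profile)) newdata[[nm]] <- profile[[nm]]
  if ("maternal_age_sq" %in% names(newdata)) {
    newdata$maternal_age_sq <- newdata$maternal_age^2
  }
  eta <- unname(predict(fit$fit, newdata = newdata, type = "link"))
  beta <- unname(coef(fit$fit)[expo])
  base <- eta - beta * c(reference, comparison)
  ci <- filter(fit$coefficients, .data$term == expo)
  decline_at <- function(b) {
    p <- plogis(base + b * c(reference, comparison))
    (p[1] - p[2]) / p[1]
  }
  p <- plogis(eta)
  out <- tibble(
    reference = reference, comparison = comparison,
    p_ref = p[1], p_cmp = p[2],
    absolute_decline = p[1] - p[2],
    relative_decline = (p[1] - p[2]) / p[1],
    relative_decline_low = min(decline_at(ci$conf_low),
                               decline_at(ci$conf_high)),
    relative_decline_high = max(decline_at(ci$conf_low),
                                decline_at(ci$conf_high))
  )
  class(out) <- c("effect_translation", class(out))
  out
}

#' Compare the base model against exposure-interaction models by AIC
#'
#' Fits the base specification and one model per interaction (exposure
#' crossed with parish, social class and sex by default) on the same rows
#' and ranks them by AIC.
#'
#' @param cohort A cohort table.
#' @param spec Base [model_spec()].
#' @param interactions Covariates to interact with the exposure.
#' @return Tibble of `model`, `aic`, `delta_aic`, ranked best-first, with the
#'   winning model first.
#' @export
compare_models <- function(cohort, spec,
                           interactions = c("parish", "social_class", "sex")) {
  interactions <- intersect(interactions, spec$covariates)
  specs <- c(list(base = spec),
             setNames(lapply(interactions, function(cv) {
               s <- spec
               s$interactions <- cv
               s
             }), paste0("exposure_x_", interactions)))
  fits <- lapply(specs, function(s) fit_model(cohort, s))
  ns <- vapply(fits, function(f) f$n_rows, numeric(1))
  if (length(unique(ns)) != 1) {
    abort("Models were fitted on differing row sets; cannot compare AIC.")
  }
  out <- tibble(
    model = names(specs),
    aic = vapply(fits, function(f) f$aic, numeric(1))
  ) |>
    arrange(.data$aic) |>
    mutate(delta_aic = .data$aic - .data$aic[1])
  out
}
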