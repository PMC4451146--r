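#' Tidy a fitness regression fit
#'
#' @param x A `wmama_fit`.
#' @param ... Unused.
#' @return Tibble of `term`, `estimate`, `std_error` (cluster-robust when a
#'   cluster was specified), `statistic`, `p_value`, `conf_low`, `conf_high`.
#' @method tidy wmama_fit
#' @export
tidy.wmama_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a fitness regression fit
#'
#' @param x A `wmama_fit`.
#' @param ... Unused.
#' @return Tibble with `outcome`, `exposure`, `family`, `n`,
#'   `exposure_estimate`, `exposure_conf_low`, `exposure_conf_high`,
#'   `permutation_p`, `log_lik`, `aic`.
#' @method glance wmama_fit
#' @export
glance.wmama_fit <- function(x, ...) {
  expo <- filter(x$coefficients, .data$term == x$spec$exposure)
  tibble(
    outcome = x$spec$outcome,
    exposure = x$spec$exposure,
    family = x$spec$family,
    n = x$n_rows,
    exposure_estimate = x$exposure_coefficient,
    exposure_conf_low = if (nrow(expo)) expo$conf_low else NA_real_,
    exposure_conf_high = if (nrow(expo)) expo$conf_high else NA_real_,
    permutation_p = x$permutation_p,
    log_lik = x$model_loglik,
    aic = x$aic
  )
}

#' Bar plot of outcome means by WMAMA quartile
#'
#' @param object A `wmama_quartiles` table from [quartile_summary()].
#' @param ... Unused.
#' @return A ggplot: per-quartile mean with ±1 SE error bars.
#' @method autoplot wmama_quartiles
#' @export
autoplot.wmama_quartiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$quartile),
                                       y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35", width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.15
    ) +
    ggplot2::labs(
      x = "WMAMA quartile",
      y = paste("Mean", attr(object, "outcome") %||% "outcome"),
      title = "Outcome by quartile of weighted mean age of male ancestors"
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitness regression
#'
#' @param object A `wmama_fit`.
#' @param ... Unused.
#' @return A ggplot: point estimates with 95% intervals on the link scale,
#'   intercept omitted.
#' @method autoplot wmama_fit
#' @export
autoplot.wmama_fit <- function(object, ...) {
  coefs <- filter(tidy(object), .data$term != "(Intercept)",
                  !startsWith(.data$term, "year_f"))
  ggplot2::ggplot(coefs, ggplot2::aes(x = .data$estimate,
                                      y = stats::reorder(.data$term,
                                                         .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2
    ) +
    ggplot2::labs(
      x = paste0("Estimate (", object$spec$family, " link scale)"),
      y = NULL,
      title = paste("Fitness model:", object$spec$outcome, "~",
                    object$spec$exposure)
    ) +
    ggplot2::theme_minimal()
}

#' De novo mutation counts against paternal age in a simulated cohort
#'
#' @param object A `simulated_cohort`.
#' @param ... Unused.
#' @return A ggplot of per-child de novo deleterious counts over paternal
#'   age with the configured linear mean overlaid.
#' @method autoplot simulated_cohort
#' @export
autoplot.simulated_cohort <- function(object, ...) {
  truth <- filter(object$truth, !is.na(.data$father_age))
  cfg <- object$config
  ggplot2::ggplot(truth, ggplot2::aes(x = .data$father_age,
                                      y = .data$k_denovo_del)) +
    ggplot2::geom_jitter(alpha = 0.2, width = 0.3, height = 0.15) +
    ggplot2::geom_function(
      fun = function(a) (cfg$lambda_ref + cfg$beta * (a - 30)) * cfg$f_del +
        cfg$maternal_denovo_point * cfg$f_del,
      colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "Paternal age at birth (years)",
      y = "De novo deleterious mutations",
      title = "Paternal-age dependence of de novo deleterious mutations"
    ) +
    ggplot2::theme_minimal()
}
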