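# Plain deterministic plot exports: forest, mediation bar, leave-one-out,
# and a harmonized-data scatter.

#' Forest plot of MR results
#'
#' Odds ratios with 95% confidence intervals, one row per exposure (and
#' method, when several are present).
#'
#' @param mr_results Tibble with columns `exposure` (or `method`), `or`,
#'   `ci_low`, `ci_high`.
#' @return A ggplot object.
#' @export
plot_forest <- function(mr_results) {
  d <- tibble::as_tibble(mr_results)
  if (!"exposure" %in% names(d)) d$exposure <- d$method
  d$label <- if (length(unique(d$method)) > 1) {
    paste(d$exposure, d$method, sep = " / ")
  } else d$exposure
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of proportions mediated
#'
#' @param mediation Tibble from [mediation_screen()] (columns `exposure`,
#'   `mediator`, `proportion_pct`).
#' @return A ggplot object.
#' @export
plot_mediation <- function(mediation) {
  d <- tibble::as_tibble(mediation)
  d$path <- paste(d$exposure, d$mediator, sep = " → ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$proportion_pct, y = .data$path)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey30") +
    ggplot2::labs(x = "Proportion of total effect mediated (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Leave-one-out plot
#'
#' @param loo Tibble from [leave_one_out()].
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  d <- tibble::as_tibble(loo)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta,
                                  y = .data$variant_id_omitted)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                                         xmax = .data$beta + 1.96 * .data$se),
                            height = 0.2) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "IVW estimate omitting the variant", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of harmonized effects
#'
#' Outcome versus exposure betas with the IVW (through the origin) and
#' MR-Egger fits overlaid.
#'
#' @param object An `mr_harmonized` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_harmonized <- function(object, ...) {
  ivw <- mr_ivw(object, "random")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           colour = "grey70", width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw$beta,
                         colour = "steelblue") +
    ggplot2::labs(x = "Effect on exposure", y = "Effect on outcome") +
    ggplot2::theme_minimal()
  if (nrow(object) >= 3) {
    egg <- mr_egger(object)
    p <- p + ggplot2::geom_abline(intercept = egg$intercept,
                                  slope = egg$beta, colour = "firebrick",
                                  linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
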