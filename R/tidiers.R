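# broom-style tidiers for list-shaped result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MR-PRESSO result
#'
#' @param x An object from [mr_presso()].
#' @param ... Unused.
#' @return Per-variant tibble of Bonferroni-adjusted outlier p-values and
#'   flags.
#' @export
tidy.mr_presso <- function(x, ...) {
  x$outliers
}

#' One-row summary of an MR-PRESSO result
#'
#' @inheritParams tidy.mr_presso
#' @return One-row tibble: global statistic and p, outlier count, distortion
#'   p, raw and outlier-corrected IVW estimates.
#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    global_rss_obs = x$global_rss_obs, global_p = x$global_p,
    n_outliers = length(x$outlier_ids),
    outlier_ids = paste(x$outlier_ids, collapse = ","),
    distortion_p = x$distortion_p,
    beta_raw = x$beta_raw$beta, se_raw = x$beta_raw$se,
    beta_outlier_corrected = x$beta_outlier_corrected$beta,
    se_outlier_corrected = x$beta_outlier_corrected$se,
    n_sim = x$n_sim)
}

#' Tidy a sensitivity report
#'
#' @param x An object from [sensitivity_report()].
#' @param ... Unused.
#' @return The per-variant leave-one-out table.
#' @export
tidy.sensitivity_report <- function(x, ...) {
  x$loo
}

#' One-row summary of a sensitivity report
#'
#' @inheritParams tidy.sensitivity_report
#' @return One-row tibble: IVW and Egger heterogeneity statistics, the Egger
#'   intercept test, and the MR-PRESSO global/distortion results.
#' @export
glance.sensitivity_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      q_stat = x$q_ivw$q, q_df = x$q_ivw$df, q_p = x$q_ivw$p_value,
      egger_q = x$q_egger$q, egger_q_df = x$q_egger$df,
      egger_q_p = x$q_egger$p_value,
      egger_intercept = x$egger$intercept,
      egger_intercept_se = x$egger$intercept_se,
      egger_intercept_p = x$egger$intercept_p),
    glance(x$presso))
}
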