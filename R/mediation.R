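# Two-step MR mediation: product-of-coefficients mediated effect and
# proportion of the total effect mediated.

extract_beta_se <- function(x, what) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1 || !all(c("beta", "se") %in% names(x))) {
      rlang::abort(paste0(what, " must be a one-row MR result with columns ",
                          "'beta' and 'se'"), class = "mrtriad_format_error")
    }
    list(beta = x$beta, se = x$se)
  } else if (is.list(x) && all(c("beta", "se") %in% names(x))) {
    list(beta = x$beta, se = x$se)
  } else {
    rlang::abort(paste0(what, " must carry 'beta' and 'se'"),
                 class = "mrtriad_format_error")
  }
}

#' Two-step MR mediation (product of coefficients)
#'
#' Combines three univariable IVW estimates on the log-odds (or linear)
#' scale: `beta1` (exposure to mediator), `beta2` (mediator to outcome) and
#' `beta3` (total exposure-to-outcome effect). The mediated effect is
#' `beta1 * beta2`, its standard error the first-order delta-method value
#' `sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)` (independence of the two steps
#' assumed, as with non-overlapping instrument sets), and the proportion of
#' the total effect mediated is `100 * beta1 * beta2 / beta3` percent. The
#' proportion is not clamped: it is negative when the indirect and total
#' effects oppose (inconsistent mediation) and can exceed 100. When
#' `|beta3| < 2 * se3` the total effect is indistinguishable from zero and
#' the proportion is flagged unstable.
#'
#' @param exp_to_med,med_to_out,exp_to_out One-row MR result tibbles (or
#'   lists with `beta` and `se`) for the three legs.
#' @param boot_ci Also compute a parametric-bootstrap percentile CI for the
#'   proportion (off by default; the point proportion is the primary
#'   report).
#' @param n_boot,conf,seed Bootstrap replicates, confidence level and seed
#'   used when `boot_ci = TRUE`.
#' @return One-row tibble of class `"mediation_result"`: `beta1`, `se1`,
#'   `beta2`, `se2`, `beta3`, `se3`, `beta_mediated`, `se_mediated`,
#'   `proportion_pct`, `direct_effect`, `unstable_proportion`, and (with
#'   `boot_ci`) `proportion_ci_low`, `proportion_ci_high`.
#' @export
two_step_mediation <- function(exp_to_med, med_to_out, exp_to_out,
                               boot_ci = FALSE, n_boot = 5000, conf = 0.95,
                               seed = NULL) {
  s1 <- extract_beta_se(exp_to_med, "exp_to_med")
  s2 <- extract_beta_se(med_to_out, "med_to_out")
  s3 <- extract_beta_se(exp_to_out, "exp_to_out")
  if (s3$beta == 0) {
    rlang::abort("total effect beta3 is zero: proportion mediated undefined",
                 class = "mrtriad_undefined_proportion_error")
  }
  beta_med <- s1$beta * s2$beta
  se_med <- sqrt(s1$beta^2 * s2$se^2 + s2$beta^2 * s1$se^2)
  out <- tibble::tibble(
    beta1 = s1$beta, se1 = s1$se,
    beta2 = s2$beta, se2 = s2$se,
    beta3 = s3$beta, se3 = s3$se,
    beta_mediated = beta_med, se_mediated = se_med,
    proportion_pct = 100 * beta_med / s3$beta,
    direct_effect = s3$beta - beta_med,
    unstable_proportion = abs(s3$beta) < 2 * s3$se)
  if (boot_ci) {
    if (!is.null(seed)) set.seed(seed)
    b1 <- stats::rnorm(n_boot, s1$beta, s1$se)
    b2 <- stats::rnorm(n_boot, s2$beta, s2$se)
    b3 <- stats::rnorm(n_boot, s3$beta, s3$se)
    prop <- 100 * b1 * b2 / b3
    qs <- stats::quantile(prop, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    out$proportion_ci_low <- qs[1]
    out$proportion_ci_high <- qs[2]
  }
  class(out) <- c("mediation_result", class(out))
  out
}

#' Screen exposure-mediator pairs for mediation
#'
#' For every exposure x mediator pair, estimates the three legs by
#' random-effects IVW after instrument selection and harmonization, and
#' emits a mediation row when all three gates hold at `alpha`:
#' (a) exposure-to-outcome significant, (b) mediator-to-outcome significant,
#' and (c) exposure-to-mediator significant. Instruments for the
#' mediator-to-outcome leg are the mediator's own.
#'
#' @param exposures,mediators Named lists of `sumstats` tibbles.
#' @param outcome Outcome `sumstats`.
#' @param config A [selection_config()] used for all three legs.
#' @param alpha Significance gate on the IVW p-values.
#' @return Tibble with one row per passing pair: `exposure`, `mediator`,
#'   `outcome`, instrument counts per leg, and all mediation fields. Empty
#'   (zero-row) when no pair passes.
#' @export
mediation_screen <- function(exposures, mediators, outcome,
                             config = selection_config(), alpha = 0.05) {
  stopifnot(is.list(exposures), is.list(mediators))
  leg <- function(exp_stats, out_stats) {
    inst <- select_instruments(exp_stats, config)
    if (nrow(inst) == 0) return(NULL)
    h <- tryCatch(
      harmonize(inst, out_stats,
                outcome_p_threshold = config$outcome_p_threshold),
      mrtriad_empty_harmonization_error = function(e) NULL)
    if (is.null(h) || nrow(h) < 2) return(NULL)
    fit <- mr_ivw(h, "random")
    fit$n_snp <- nrow(h)
    fit
  }
  rows <- list()
  fits_exp_out <- purrr::map(exposures, leg, out_stats = outcome)
  fits_med_out <- purrr::map(mediators, leg, out_stats = outcome)
  for (ei in seq_along(exposures)) {
    f3 <- fits_exp_out[[ei]]
    if (is.null(f3) || f3$p_value >= alpha) next
    for (mi in seq_along(mediators)) {
      f2 <- fits_med_out[[mi]]
      if (is.null(f2) || f2$p_value >= alpha) next
      f1 <- leg(exposures[[ei]], mediators[[mi]])
      if (is.null(f1) || f1$p_value >= alpha) next
      med <- two_step_mediation(f1, f2, f3)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(
          exposure = names(exposures)[ei] %||% trait_id(exposures[[ei]]),
          mediator = names(mediators)[mi] %||% trait_id(mediators[[mi]]),
          outcome = trait_id(outcome),
          n_snp_exp_med = f1$n_snp, n_snp_med_out = f2$n_snp,
          n_snp_exp_out = f3$n_snp),
        tibble::as_tibble(med))
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(exposure = character(0), mediator = character(0),
                          outcome = character(0)))
  }
  dplyr::bind_rows(rows)
}
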