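# Sensitivity diagnostics: Cochran's Q, MR-PRESSO, leave-one-out.

#' Cochran's Q heterogeneity test
#'
#' Heterogeneity of per-variant causal estimates around the IVW slope
#' (df `k - 1`) or around the MR-Egger fit (df `k - 2`), with a chi-square
#' p-value. The IVW Q computed here is identical to the one that scales the
#' random-effects IVW standard error.
#'
#' @param h Harmonized data.
#' @param model `"ivw"` or `"egger"`.
#' @return One-row tibble: `model`, `q`, `df`, `p_value`.
#' @export
cochran_q <- function(h, model = c("ivw", "egger")) {
  model <- match.arg(model)
  qinfo <- if (model == "ivw") {
    attr(mr_ivw(h, "fixed"), "q")
  } else {
    attr(mr_egger(h), "q")
  }
  tibble::tibble(model = model, q = qinfo$q, df = as.integer(qinfo$df),
                 p_value = stats::pchisq(qinfo$q, qinfo$df,
                                         lower.tail = FALSE))
}

# Leave-one-out IVW slopes from running sums; w = 1/se_out^2.
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Detects horizontal-pleiotropy outliers by comparing observed residuals to
#' a simulated null. For each variant `j` the leave-one-out IVW slope
#' `theta_(-j)` gives a residual `beta_out_j - theta_(-j) * beta_exp_j`; the
#' observed global statistic is the sum of squared residuals (RSS). The null
#' distribution is built from `n_sim` parametric simulations drawing
#' `beta_out_j* ~ N(theta_(-j) * beta_exp_j, se_out_j^2)` and
#' `beta_exp_j* ~ N(beta_exp_j, se_exp_j^2)` and recomputing the RSS the
#' same way. Empirical p-values use the `(1 + b) / (1 + n_sim)` correction,
#' so zero is impossible. Per-variant outlier p-values are
#' Bonferroni-multiplied by `k`; variants below `outlier_alpha` are flagged.
#' The distortion test compares the outlier-corrected IVW slope against the
#' distribution of slopes obtained by removing equally many random variants.
#'
#' @param h Harmonized data with at least four variants.
#' @param n_sim Simulation replicates (default 1000).
#' @param outlier_alpha Flagging threshold on the Bonferroni-adjusted
#'   per-variant p-values.
#' @param seed RNG seed; p-values are invariant to variant order given the
#'   same seed.
#' @param distortion_sided `"two"` (default) or `"one"` (greater).
#' @return A list of class `"mr_presso"`: `global_rss_obs`, `global_p`,
#'   `outliers` (per-variant tibble with adjusted p-values and flags),
#'   `outlier_ids`, `distortion_p`, `beta_raw`, `beta_outlier_corrected`
#'   (random-effects IVW rows), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = NULL,
                      distortion_sided = c("two", "one")) {
  distortion_sided <- match.arg(distortion_sided)
  check_h(h, 4, "mr_presso")
  k <- nrow(h)
  # canonical variant order so results do not depend on row order
  ids <- if ("variant_id" %in% names(h)) h$variant_id else
    sprintf("snp_%03d", seq_len(k))
  ord <- order(ids)
  h <- h[ord, , drop = FALSE]
  ids <- ids[ord]
  if (!is.null(seed)) set.seed(seed)

  bx <- h$beta_exp; by <- h$beta_out
  sx <- h$se_exp; sy <- h$se_out
  w <- 1 / sy^2

  theta_loo <- loo_slopes(bx, by, w)
  resid_obs <- by - theta_loo * bx
  rss_obs <- sum(resid_obs^2)

  # simulated null: matrices k x n_sim
  bx_sim <- matrix(stats::rnorm(k * n_sim, bx, sx), nrow = k)
  by_sim <- matrix(stats::rnorm(k * n_sim, theta_loo * bx, sy), nrow = k)
  sxy <- colSums(w * bx_sim * by_sim)
  sxx <- colSums(w * bx_sim^2)
  theta_sim <- sweep(-(w * bx_sim * by_sim), 2, sxy, `+`) /
    sweep(-(w * bx_sim^2), 2, sxx, `+`)
  resid_sim <- by_sim - theta_sim * bx_sim
  rss_sim <- colSums(resid_sim^2)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_raw <- (1 + rowSums(resid_sim^2 >= resid_obs^2)) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * k)
  is_outlier <- p_adj < outlier_alpha
  outlier_ids <- ids[is_outlier]
  if (all(is_outlier)) {
    rlang::abort("all variants flagged as outliers; no corrected estimate possible",
                 class = "mrtriad_degenerate_correction_error")
  }

  beta_raw <- mr_ivw(h, "random")
  n_out <- sum(is_outlier)
  if (n_out > 0) {
    h_keep <- h[!is_outlier, , drop = FALSE]
    beta_corr <- mr_ivw(h_keep, "random")
    # distortion: slopes after removing equally many random variants
    slope_rand <- vapply(seq_len(n_sim), function(b) {
      drop <- sample.int(k, n_out)
      ivw_slope(bx[-drop], by[-drop], w[-drop])
    }, numeric(1))
    obs <- beta_corr$beta
    p_ge <- (1 + sum(slope_rand >= obs)) / (n_sim + 1)
    p_le <- (1 + sum(slope_rand <= obs)) / (n_sim + 1)
    distortion_p <- if (distortion_sided == "two") {
      min(1, 2 * min(p_ge, p_le))
    } else {
      p_ge
    }
  } else {
    beta_corr <- beta_raw
    distortion_p <- NA_real_
  }

  structure(list(
    global_rss_obs = rss_obs,
    global_p = global_p,
    outliers = tibble::tibble(variant_id = ids, p_value = p_adj,
                              outlier = is_outlier),
    outlier_ids = outlier_ids,
    distortion_p = distortion_p,
    beta_raw = beta_raw,
    beta_outlier_corrected = beta_corr,
    n_sim = n_sim,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("MR-PRESSO (", x$n_sim, " simulations)\n", sep = "")
  cat("  global RSS:", format(x$global_rss_obs, digits = 4),
      " p =", format(x$global_p, digits = 3), "\n")
  cat("  outliers:", if (length(x$outlier_ids) == 0) "none"
      else paste(x$outlier_ids, collapse = ", "), "\n")
  if (!is.na(x$distortion_p)) {
    cat("  distortion p =", format(x$distortion_p, digits = 3), "\n")
  }
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Refits the random-effects IVW estimator `k` times, omitting one variant
#' each time, and flags omissions that flip the sign of the estimate or move
#' its p-value across `alpha` relative to the full fit.
#'
#' @param h Harmonized data with at least three variants.
#' @param alpha Significance level for the crossing flag.
#' @return Tibble with one row per omitted variant: `variant_id_omitted`,
#'   `beta`, `se`, `p_value`, `sign_change`, `p_crosses_alpha`.
#' @export
leave_one_out <- function(h, alpha = 0.05) {
  check_h(h, 3, "leave_one_out")
  k <- nrow(h)
  full <- mr_ivw(h, "random")
  ids <- if ("variant_id" %in% names(h)) h$variant_id else
    sprintf("snp_%03d", seq_len(k))
  rows <- purrr::map(seq_len(k), function(j) {
    fit <- mr_ivw(h[-j, , drop = FALSE], "random")
    tibble::tibble(variant_id_omitted = ids[j], beta = fit$beta, se = fit$se,
                   p_value = fit$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$sign_change <- sign(out$beta) != sign(full$beta)
  out$p_crosses_alpha <- (out$p_value < alpha) != (full$p_value < alpha)
  out
}

#' Full sensitivity battery for one exposure-outcome pair
#'
#' Bundles Cochran's Q (IVW and Egger), the MR-Egger intercept test,
#' MR-PRESSO and the leave-one-out analysis.
#'
#' @param h Harmonized data with at least four variants.
#' @param n_sim MR-PRESSO simulation replicates.
#' @param seed RNG seed for MR-PRESSO.
#' @return A list of class `"sensitivity_report"` with elements `q_ivw`,
#'   `q_egger`, `egger` (the full Egger result row), `presso`, `loo`.
#'   Use [generics::glance()] for a one-row summary.
#' @export
sensitivity_report <- function(h, n_sim = 1000, seed = NULL) {
  check_h(h, 4, "sensitivity_report")
  egger_row <- mr_egger(h)
  structure(list(
    q_ivw = cochran_q(h, "ivw"),
    q_egger = cochran_q(h, "egger"),
    egger = egger_row,
    presso = mr_presso(h, n_sim = n_sim, seed = seed),
    loo = leave_one_out(h)),
    class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  print(glance(x))
  invisible(x)
}
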