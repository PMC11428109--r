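# Causal estimators on harmonized exposure-outcome data.
#
# All estimators take a harmonized table (columns beta_exp, se_exp, beta_out,
# se_out) and return a one-row tibble with a common set of columns, so
# results from several methods and trait pairs row-bind into a tidy table.

mr_result_row <- function(method, n_snp, beta, se, p_value,
                          intercept = NA_real_, intercept_se = NA_real_,
                          intercept_p = NA_real_, seed = NA_integer_) {
  tibble::tibble(
    method = method, n_snp = as.integer(n_snp), beta = beta, se = se,
    p_value = p_value, or = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    intercept = intercept, intercept_se = intercept_se,
    intercept_p = intercept_p, seed = seed)
}

check_h <- function(h, min_snp, method) {
  needed <- c("beta_exp", "se_exp", "beta_out", "se_out")
  missing <- setdiff(needed, names(h))
  if (length(missing) > 0) {
    rlang::abort(paste0("harmonized data lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "mrtriad_format_error")
  }
  if (nrow(h) < min_snp) {
    rlang::abort(paste0(method, " requires at least ", min_snp,
                        " variants; got ", nrow(h)),
                 class = "mrtriad_insufficient_instruments_error")
  }
  invisible(h)
}

#' Wald ratio for a single instrument
#'
#' The per-variant causal estimate `beta_out / beta_exp`, with the
#' first-order delta-method standard error `se_out / |beta_exp|` (the
#' exposure beta treated as fixed).
#'
#' @param h Harmonized data with exactly one variant.
#' @return One-row tibble of MR-result columns (`method = "wald"`).
#' @export
mr_wald_ratio <- function(h) {
  check_h(h, 1, "wald_ratio")
  if (nrow(h) != 1) {
    rlang::abort("wald_ratio takes exactly one variant",
                 class = "mrtriad_insufficient_instruments_error")
  }
  if (h$beta_exp == 0) {
    rlang::abort("degenerate instrument: exposure beta is zero",
                 class = "mrtriad_degenerate_instrument_error")
  }
  beta <- h$beta_out / h$beta_exp
  se <- h$se_out / abs(h$beta_exp)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_result_row("wald", 1L, beta, se, p)
}

# IVW slope from precomputed sums; shared by estimators and sensitivity code.
ivw_slope <- function(bx, by, w) {
  sum(w * bx * by) / sum(w * bx^2)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin, weights `1/se_out^2` (equivalently an inverse-variance
#' meta-analysis of per-variant Wald ratios). Cochran's Q over the
#' regression residuals measures heterogeneity. The random-effects model is
#' multiplicative: the fixed-effect standard error is inflated by
#' `max(1, sqrt(Q / (k - 1)))`, so it never falls below the fixed-effect
#' one. P-values are two-sided normal.
#'
#' @param h Harmonized data with at least two variants.
#' @param model `"random"` (default) or `"fixed"`.
#' @return One-row tibble of MR-result columns, plus attribute `q`, a list
#'   with the heterogeneity statistic (`q`, `df`).
#' @export
mr_ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  check_h(h, 2, "ivw")
  k <- nrow(h)
  w <- 1 / h$se_out^2
  beta <- ivw_slope(h$beta_exp, h$beta_out, w)
  se_fixed <- sqrt(1 / sum(w * h$beta_exp^2))
  q <- sum(w * (h$beta_out - beta * h$beta_exp)^2)
  se <- if (model == "random") se_fixed * max(1, sqrt(q / (k - 1))) else se_fixed
  p <- 2 * stats::pnorm(-abs(beta / se))
  out <- mr_result_row(if (model == "random") "ivw_re" else "ivw_fe",
                       k, beta, se, p)
  attr(out, "q") <- list(q = q, df = k - 1)
  out
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' unconstrained intercept (weights `1/se_out^2`). The slope is a
#' pleiotropy-adjusted causal estimate; the intercept estimates average
#' directional pleiotropy. Variants are first oriented so every exposure
#' beta is non-negative. Standard errors of both coefficients use
#' multiplicative random-effects scaling `max(1, sqrt(Q_egger / (k - 2)))`
#' and p-values come from a t distribution with `k - 2` degrees of freedom.
#'
#' @param h Harmonized data with at least three variants.
#' @return One-row tibble of MR-result columns with the intercept fields
#'   populated, plus attribute `q` (Egger residual Q, df `k - 2`).
#' @export
mr_egger <- function(h) {
  check_h(h, 3, "egger")
  k <- nrow(h)
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  w <- 1 / h$se_out^2

  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  denom <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / denom
  intercept <- (swy - slope * swx) / sw
  resid <- by - intercept - slope * bx
  q <- sum(w * resid^2)
  scale <- max(1, sqrt(q / (k - 2)))
  se_slope <- sqrt(sw / denom) * scale
  se_int <- sqrt(swxx / denom) * scale
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = k - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = k - 2)
  out <- mr_result_row("egger", k, slope, se_slope, p_slope,
                       intercept = intercept, intercept_se = se_int,
                       intercept_p = p_int)
  attr(out, "q") <- list(q = q, df = k - 2)
  out
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(theta[1])
  if (s[length(s)] <= 0.5) return(theta[length(theta)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE over a point-estimator of (bx, by).
bootstrap_se <- function(h, point_fun, n_boot, seed) {
  if (n_boot <= 0) return(NA_real_)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(h)
  est <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, h$beta_exp, h$se_exp)
    by <- stats::rnorm(k, h$beta_out, h$se_out)
    point_fun(bx, by)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted-median estimator
#'
#' Median of per-variant Wald ratios weighted by `beta_exp^2 / se_out^2`,
#' computed by linear interpolation of the cumulative standardized weights
#' at 0.5. Consistent when instruments carrying at least half of the weight
#' are valid. The standard error comes from a seeded parametric bootstrap
#' (resampling each beta from a normal with its reported SE); set
#' `n_boot = 0` to skip it (SE and p returned as `NA`).
#'
#' @param h Harmonized data with at least three variants.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap; recorded in the result.
#' @return One-row tibble of MR-result columns (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  check_h(h, 3, "weighted_median")
  point <- function(bx, by) weighted_median_point(by / bx, bx^2 / h$se_out^2)
  beta <- point(h$beta_exp, h$beta_out)
  se <- bootstrap_se(h, point, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  mr_result_row("weighted_median", nrow(h), beta, se, p,
                seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

mode_point <- function(theta, w, phi) {
  k <- length(theta)
  s <- stats::sd(theta)
  m <- stats::mad(theta)  # default constant 1.4826 = raw MAD / 0.6745
  cand <- c(s, m)
  cand <- cand[is.finite(cand) & cand > 0]  # mad collapses to 0 under ties
  if (length(cand) == 0) return(theta[1])   # all ratios identical
  h_bw <- phi * 0.9 * min(cand) * k^(-1 / 5)
  grid <- c(theta, seq(min(theta), max(theta), length.out = 512))
  w <- w / sum(w)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, theta, h_bw)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimators (simple and weighted mode)
#'
#' The mode of the smoothed empirical density of per-variant Wald ratios,
#' with a normal kernel and bandwidth
#' `phi * 0.9 * min(sd, mad) * k^(-1/5)` (the modified Silverman rule;
#' `mad` is the normal-consistent median absolute deviation). The weighted
#' variant weights each kernel by the normalized `beta_exp^2 / se_out^2`;
#' the simple variant uses equal weights. The density is evaluated at the
#' ratio estimates themselves plus a 512-point grid spanning them. If all
#' ratios coincide the common value is returned. SE by seeded parametric
#' bootstrap, as in [mr_weighted_median()].
#'
#' @param h Harmonized data with at least three variants.
#' @param weighted Use inverse-variance kernel weights (`TRUE`) or equal
#'   weights (`FALSE`).
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return One-row tibble of MR-result columns (`method = "weighted_mode"`
#'   or `"simple_mode"`).
#' @export
mr_mode <- function(h, weighted = TRUE, phi = 1, n_boot = 1000, seed = NULL) {
  check_h(h, 3, "mode")
  point <- function(bx, by) {
    theta <- by / bx
    w <- if (weighted) bx^2 / h$se_out^2 else rep(1, length(theta))
    mode_point(theta, w, phi)
  }
  beta <- point(h$beta_exp, h$beta_out)
  se <- bootstrap_se(h, point, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  mr_result_row(if (weighted) "weighted_mode" else "simple_mode",
                nrow(h), beta, se, p,
                seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Run the full panel of MR estimators
#'
#' Applies random-effects IVW (the primary method), MR-Egger, weighted
#' median, simple mode and weighted mode to one harmonized exposure-outcome
#' pair. With a single variant, falls back to the Wald ratio; with two,
#' only IVW is computed.
#'
#' @param h Harmonized data.
#' @param n_boot Bootstrap replicates for the median/mode standard errors.
#' @param seed RNG seed for the bootstraps.
#' @return Tibble with one row per method, plus columns `exposure` and
#'   `outcome` (trait ids, when present as attributes of `h`).
#' @export
mr_all <- function(h, n_boot = 1000, seed = NULL) {
  check_h(h, 1, "mr_all")
  res <- if (nrow(h) == 1) {
    mr_wald_ratio(h)
  } else if (nrow(h) == 2) {
    mr_ivw(h, "random")
  } else {
    dplyr::bind_rows(
      mr_ivw(h, "random"),
      mr_egger(h),
      mr_weighted_median(h, n_boot = n_boot, seed = seed),
      mr_mode(h, weighted = FALSE, n_boot = n_boot, seed = seed),
      mr_mode(h, weighted = TRUE, n_boot = n_boot, seed = seed))
  }
  exposure <- attr(h, "exposure_id", exact = TRUE)
  outcome <- attr(h, "outcome_id", exact = TRUE)
  dplyr::bind_cols(
    tibble::tibble(exposure = rep(exposure %||% NA_character_, nrow(res)),
                   outcome = rep(outcome %||% NA_character_, nrow(res))),
    res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
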