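# Synthetic GWAS summary statistics with known causal structure.
#
# Everything is simulated directly at the summary level: per-variant
# instrument effects are drawn, then reported betas are the true effects
# plus Gaussian estimation noise with the standard error implied by the
# allele frequency and sample size, se = 1/sqrt(2*maf*(1-maf)*N).

#' Configuration for the synthetic GWAS generator
#'
#' @param n_snps Number of instrument variants for the exposure.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (individuals) for
#'   the exposure, mediator and outcome studies. Defaults emulate a small
#'   immunophenotype GWAS (3,757), a mid-size metabolite GWAS (8,000) and a
#'   large case-control outcome GWAS analysed on the log-odds scale (470,002).
#' @param theta True causal effect of the exposure on the outcome (log-odds
#'   per SD, or linear). Used by [simulate_gwas_pair()].
#' @param theta1,theta2,theta_direct Mediation-path effects:
#'   exposure to mediator, mediator to outcome, and the direct
#'   exposure-to-outcome effect. Used by [simulate_mediation_triangle()];
#'   the implied total effect is `theta_direct + theta1 * theta2` by
#'   construction.
#' @param sigma_gamma SD of true instrument effect magnitudes. Instrument
#'   effects are drawn as `|Normal(0, sigma_gamma^2)|`, i.e. oriented so the
#'   effect allele increases the exposure, the convention under which
#'   directional pleiotropy is defined.
#' @param prop_invalid Fraction of exposure instruments with horizontal
#'   pleiotropy, in `[0, 1]`. Exactly `round(prop_invalid * n_snps)` variants
#'   receive a nonzero pleiotropic effect.
#' @param mu_alpha,sigma_alpha Mean and SD of the pleiotropic (direct-on-
#'   outcome) effects of invalid instruments.
#' @param maf_range Length-2 numeric, minor-allele-frequency bounds in
#'   `(0, 0.5]`.
#' @param palindrome_fraction Fraction of variants assigned strand-ambiguous
#'   (A/T or C/G) allele pairs, to exercise the palindromic-variant filter.
#'   Exactly `round(palindrome_fraction * n_snps)` variants are palindromic.
#' @param n_mediator_snps Number of mediator-specific instruments generated
#'   by [simulate_mediation_triangle()] (default: `n_snps`).
#' @param position_gap_kb Spacing (kb) between consecutive variants on the
#'   single synthetic chromosome. The default (20,000 kb) exceeds the usual
#'   10,000 kb clumping window so independently drawn instruments survive
#'   distance-only clumping.
#' @param seed Integer RNG seed; the same configuration yields byte-identical
#'   output.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_snps = 100,
                       n_exposure = 3757,
                       n_mediator = 8000,
                       n_outcome = 470002,
                       theta = 0,
                       theta1 = NA_real_,
                       theta2 = NA_real_,
                       theta_direct = NA_real_,
                       sigma_gamma = 0.1,
                       prop_invalid = 0,
                       mu_alpha = 0,
                       sigma_alpha = 0.02,
                       maf_range = c(0.05, 0.5),
                       palindrome_fraction = 0,
                       n_mediator_snps = n_snps,
                       position_gap_kb = 20000,
                       seed = 1L) {
  cfg <- list(n_snps = n_snps, n_exposure = n_exposure,
              n_mediator = n_mediator, n_outcome = n_outcome,
              theta = theta, theta1 = theta1, theta2 = theta2,
              theta_direct = theta_direct, sigma_gamma = sigma_gamma,
              prop_invalid = prop_invalid, mu_alpha = mu_alpha,
              sigma_alpha = sigma_alpha, maf_range = maf_range,
              palindrome_fraction = palindrome_fraction,
              n_mediator_snps = n_mediator_snps,
              position_gap_kb = position_gap_kb, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    rlang::abort(paste0("invalid simulation configuration: field '", field,
                        "' ", why),
                 class = "mrtriad_config_error")
  }
  scalar_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x)
  if (!scalar_count(cfg$n_snps) || cfg$n_snps < 1) fail("n_snps", "must be >= 1")
  for (f in c("n_exposure", "n_mediator", "n_outcome")) {
    if (!scalar_count(cfg[[f]]) || cfg[[f]] < 2) fail(f, "must be >= 2")
  }
  if (!scalar_count(cfg$sigma_gamma) || cfg$sigma_gamma <= 0) {
    fail("sigma_gamma", "must be > 0")
  }
  if (!scalar_count(cfg$prop_invalid) || cfg$prop_invalid < 0 ||
      cfg$prop_invalid > 1) {
    fail("prop_invalid", "must lie in [0, 1]")
  }
  if (!scalar_count(cfg$sigma_alpha) || cfg$sigma_alpha < 0) {
    fail("sigma_alpha", "must be >= 0")
  }
  mr <- cfg$maf_range
  if (!is.numeric(mr) || length(mr) != 2 || any(is.na(mr)) ||
      mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2]) {
    fail("maf_range", "must be ordered bounds within (0, 0.5]")
  }
  if (!scalar_count(cfg$palindrome_fraction) || cfg$palindrome_fraction < 0 ||
      cfg$palindrome_fraction > 1) {
    fail("palindrome_fraction", "must lie in [0, 1]")
  }
  if (!scalar_count(cfg$position_gap_kb) || cfg$position_gap_kb <= 0) {
    fail("position_gap_kb", "must be > 0")
  }
  if (!scalar_count(cfg$seed)) fail("seed", "must be a single integer")
  invisible(cfg)
}

# Draw allele pairs: `n_pal` strand-ambiguous pairs, the rest unambiguous.
draw_alleles <- function(n, palindrome_fraction) {
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  all_pairs <- expand.grid(ea = bases, oa = bases, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$ea != all_pairs$oa, ]
  nonpal <- all_pairs[comp[all_pairs$ea] != all_pairs$oa, ]

  n_pal <- round(palindrome_fraction * n)
  idx_pal <- if (n_pal > 0) sample.int(n, n_pal) else integer(0)
  ea <- oa <- character(n)
  k_np <- sample.int(nrow(nonpal), n, replace = TRUE)
  ea <- nonpal$ea[k_np]
  oa <- nonpal$oa[k_np]
  if (n_pal > 0) {
    k_p <- sample.int(4, n_pal, replace = TRUE)
    ea[idx_pal] <- vapply(pal_pairs[k_p], `[`, "", 1)
    oa[idx_pal] <- vapply(pal_pairs[k_p], `[`, "", 2)
  }
  list(effect_allele = ea, other_allele = oa)
}

# Assemble a sumstats tibble from true effects + sampling noise.
reported_trait <- function(ids, chrom, pos, alleles, maf, true_beta, n,
                           trait_id, trait_name = trait_id) {
  se <- 1 / sqrt(2 * maf * (1 - maf) * n)
  beta <- stats::rnorm(length(ids), mean = true_beta, sd = se)
  p <- 2 * stats::pnorm(-abs(beta / se))
  p <- pmax(p, .Machine$double.xmin)  # keep within (0, 1]
  sumstats(tibble::tibble(
    variant_id = ids, chromosome = chrom, base_pair_location = pos,
    effect_allele = alleles$effect_allele, other_allele = alleles$other_allele,
    effect_allele_frequency = maf, beta = beta, standard_error = se,
    p_value = p, n = n), trait_id = trait_id, trait_name = trait_name,
    quiet = TRUE)
}

# Pleiotropic effects: exactly round(prop_invalid * n) variants nonzero.
draw_pleiotropy <- function(n, prop_invalid, mu_alpha, sigma_alpha) {
  n_invalid <- n - round((1 - prop_invalid) * n)
  alpha <- numeric(n)
  if (n_invalid > 0) {
    idx <- sample.int(n, n_invalid)
    alpha[idx] <- stats::rnorm(n_invalid, mu_alpha, sigma_alpha)
  }
  alpha
}

#' Simulate an exposure-outcome pair of GWAS summary tables
#'
#' For variant `j`: `maf_j ~ Uniform(maf_range)`; the true instrument effect
#' is `gamma_j = |Normal(0, sigma_gamma^2)|`; with probability mass
#' `prop_invalid` (exact count) the variant carries a pleiotropic effect
#' `alpha_j ~ Normal(mu_alpha, sigma_alpha^2)`, else `alpha_j = 0`. The true
#' outcome association is `Gamma_j = theta * gamma_j + alpha_j`. Reported
#' betas add Gaussian estimation noise with
#' `se_j = 1/sqrt(2 * maf_j * (1 - maf_j) * N)`; p-values are two-sided
#' normal. Variants sit on one synthetic chromosome at uniform spacing.
#'
#' @param config A [sim_config()].
#' @return A list with elements `exposure` and `outcome` (validated
#'   `sumstats` tibbles sharing variant ids, alleles and frequencies) and
#'   `truth`, a tibble of per-variant `gamma`, `alpha` and the trait-level
#'   `theta`.
#' @export
simulate_gwas_pair <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_snps
  ids <- sprintf("rs%06d", seq_len(n))
  pos <- seq_len(n) * config$position_gap_kb * 1000
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  alleles <- draw_alleles(n, config$palindrome_fraction)
  gamma <- abs(stats::rnorm(n, 0, config$sigma_gamma))
  alpha <- draw_pleiotropy(n, config$prop_invalid, config$mu_alpha,
                           config$sigma_alpha)
  Gamma <- config$theta * gamma + alpha

  exposure <- reported_trait(ids, "1", pos, alleles, maf, gamma,
                             config$n_exposure, "exposure")
  outcome <- reported_trait(ids, "1", pos, alleles, maf, Gamma,
                            config$n_outcome, "outcome")
  truth <- tibble::tibble(variant_id = ids, gamma = gamma, alpha = alpha,
                          theta = config$theta)
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate an exposure-mediator-outcome triangle
#'
#' Generates three GWAS summary tables with a known mediation structure.
#' Exposure instruments act on the mediator with slope `theta1` and on the
#' outcome with slope `theta_direct + theta1 * theta2` (plus any pleiotropy);
#' an independent set of mediator-specific instruments (null on the exposure)
#' acts on the outcome with slope `theta2`, so the mediator-to-outcome leg
#' has valid instruments of its own. All three tables cover the union of
#' both variant sets, as genome-wide scans would.
#'
#' @param config A [sim_config()] with `theta1`, `theta2` and `theta_direct`
#'   set. The implied total effect `theta_direct + theta1 * theta2` must be
#'   nonzero, otherwise the true proportion mediated is undefined.
#' @return A list with `exposure`, `mediator`, `outcome` (`sumstats`
#'   tibbles) and `truth`, a tibble carrying per-variant true effects, the
#'   instrument-set label, and the trait-level `theta1`, `theta2`,
#'   `theta_direct`, `theta_total` and `true_proportion_pct`.
#' @export
simulate_mediation_triangle <- function(config) {
  validate_sim_config(config)
  for (f in c("theta1", "theta2", "theta_direct")) {
    if (is.na(config[[f]])) {
      rlang::abort(paste0("invalid simulation configuration: field '", f,
                          "' must be set for a mediation triangle"),
                   class = "mrtriad_config_error")
    }
  }
  total <- config$theta_direct + config$theta1 * config$theta2
  if (total == 0) {
    rlang::abort(paste0("invalid simulation configuration: field ",
                        "'theta_direct' implies a zero total effect; the ",
                        "true proportion mediated is undefined"),
                 class = "mrtriad_config_error")
  }
  set.seed(config$seed)
  n_e <- config$n_snps
  n_m <- config$n_mediator_snps
  n <- n_e + n_m
  ids <- sprintf("rs%06d", seq_len(n))
  set_lab <- rep(c("exposure_instrument", "mediator_instrument"),
                 c(n_e, n_m))
  pos <- seq_len(n) * config$position_gap_kb * 1000
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  alleles <- draw_alleles(n, config$palindrome_fraction)

  effect <- abs(stats::rnorm(n, 0, config$sigma_gamma))
  gamma <- ifelse(set_lab == "exposure_instrument", effect, 0)
  delta <- ifelse(set_lab == "mediator_instrument", effect, 0)
  alpha <- draw_pleiotropy(n, config$prop_invalid, config$mu_alpha,
                           config$sigma_alpha)

  true_exp <- gamma
  true_med <- config$theta1 * gamma + delta
  true_out <- total * gamma + config$theta2 * delta + alpha

  exposure <- reported_trait(ids, "1", pos, alleles, maf, true_exp,
                             config$n_exposure, "exposure")
  mediator <- reported_trait(ids, "1", pos, alleles, maf, true_med,
                             config$n_mediator, "mediator")
  outcome <- reported_trait(ids, "1", pos, alleles, maf, true_out,
                            config$n_outcome, "outcome")
  truth <- tibble::tibble(
    variant_id = ids, instrument_set = set_lab, gamma = gamma, delta = delta,
    alpha = alpha, theta1 = config$theta1, theta2 = config$theta2,
    theta_direct = config$theta_direct, theta_total = total,
    true_proportion_pct = 100 * config$theta1 * config$theta2 / total)
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}

#' Simulate a multi-trait synthetic study
#'
#' Builds a small study of several exposures and mediators sharing one
#' outcome, each trait with its own disjoint instrument set. Exposure
#' `i` has causal effect `theta_exposures[i]` on the outcome; one optional
#' mediated path runs from the first exposure through the first mediator
#' (`theta1`/`theta2`/`theta_direct` from `config`, overriding that
#' exposure's total effect). Mediator `m` affects the outcome with slope
#' `theta_mediators[m]`.
#'
#' @param n_exposures,n_mediators Number of exposure and mediator traits.
#' @param theta_exposures Numeric vector of true total exposure effects
#'   (recycled to length `n_exposures`).
#' @param theta_mediators Numeric vector of true mediator-on-outcome effects
#'   (recycled to length `n_mediators`).
#' @param mediated_path If `TRUE` (and the triangle effects are set in
#'   `config`), exposure 1 acts on mediator 1 with slope `theta1` and its
#'   total outcome effect is `theta_direct + theta1 * theta2`.
#' @param config A [sim_config()]; `n_snps` instruments are generated per
#'   trait.
#' @return A list with `exposures` and `mediators` (named lists of
#'   `sumstats`), `outcome`, and a `truth` tibble of trait-level effects.
#' @export
simulate_study <- function(n_exposures = 5, n_mediators = 3,
                           theta_exposures = 0, theta_mediators = 0,
                           mediated_path = FALSE, config = sim_config()) {
  validate_sim_config(config)
  theta_exposures <- rep_len(theta_exposures, n_exposures)
  theta_mediators <- rep_len(theta_mediators, n_mediators)
  theta1 <- 0
  if (mediated_path) {
    for (f in c("theta1", "theta2", "theta_direct")) {
      if (is.na(config[[f]])) {
        rlang::abort(paste0("invalid simulation configuration: field '", f,
                            "' must be set when mediated_path = TRUE"),
                     class = "mrtriad_config_error")
      }
    }
    theta1 <- config$theta1
    theta_mediators[1] <- config$theta2
    theta_exposures[1] <- config$theta_direct + config$theta1 * config$theta2
  }
  set.seed(config$seed)
  k <- config$n_snps
  n_traits <- n_exposures + n_mediators
  n <- k * n_traits
  ids <- sprintf("rs%06d", seq_len(n))
  pos <- seq_len(n) * config$position_gap_kb * 1000
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  alleles <- draw_alleles(n, config$palindrome_fraction)
  effect <- abs(stats::rnorm(n, 0, config$sigma_gamma))
  owner <- rep(seq_len(n_traits), each = k)  # trait owning each instrument

  # true per-variant effect of each trait, and on the outcome
  true_out <- numeric(n)
  exposures <- vector("list", n_exposures)
  names(exposures) <- sprintf("exposure_%02d", seq_len(n_exposures))
  mediators <- vector("list", n_mediators)
  names(mediators) <- sprintf("mediator_%02d", seq_len(n_mediators))

  for (i in seq_len(n_exposures)) {
    own <- owner == i
    true_out[own] <- true_out[own] + theta_exposures[i] * effect[own]
  }
  for (m in seq_len(n_mediators)) {
    own <- owner == n_exposures + m
    true_out[own] <- true_out[own] + theta_mediators[m] * effect[own]
  }
  alpha <- draw_pleiotropy(n, config$prop_invalid, config$mu_alpha,
                           config$sigma_alpha)
  true_out <- true_out + alpha

  for (i in seq_len(n_exposures)) {
    true_i <- ifelse(owner == i, effect, 0)
    exposures[[i]] <- reported_trait(ids, "1", pos, alleles, maf, true_i,
                                     config$n_exposure, names(exposures)[i])
  }
  for (m in seq_len(n_mediators)) {
    true_m <- ifelse(owner == n_exposures + m, effect, 0)
    if (mediated_path && m == 1) {
      # exposure 1's instruments act on mediator 1 with slope theta1
      true_m <- true_m + ifelse(owner == 1, theta1 * effect, 0)
    }
    mediators[[m]] <- reported_trait(ids, "1", pos, alleles, maf, true_m,
                                     config$n_mediator, names(mediators)[m])
  }
  outcome <- reported_trait(ids, "1", pos, alleles, maf, true_out,
                            config$n_outcome, "outcome")
  truth <- tibble::tibble(
    trait_id = c(names(exposures), names(mediators)),
    role = rep(c("exposure", "mediator"), c(n_exposures, n_mediators)),
    theta_on_outcome = c(theta_exposures, theta_mediators))
  list(exposures = exposures, mediators = mediators, outcome = outcome,
       truth = truth)
}
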