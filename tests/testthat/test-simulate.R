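test_that("no-pleiotropy configurations produce all-zero pleiotropic effects", {
  sim <- simulate_gwas_pair(sim_config(n_snps = 40, prop_invalid = 0,
                                       sigma_alpha = 0, seed = 11))
  expect_true(all(sim$truth$alpha == 0))
  # exact invalid count under a fractional setting
  sim2 <- simulate_gwas_pair(sim_config(n_snps = 40, prop_invalid = 0.25,
                                        mu_alpha = 0.05, seed = 11))
  expect_equal(sum(sim2$truth$alpha != 0), 10)
})

test_that("palindromic allele pairs appear at exactly the configured count", {
  sim <- simulate_gwas_pair(sim_config(n_snps = 50, palindrome_fraction = 0.2,
                                       seed = 5))
  pal <- with(sim$exposure, paste(effect_allele, other_allele)) %in%
    c("A T", "T A", "C G", "G C")
  expect_equal(sum(pal), 10)
  expect_identical(sim$exposure$effect_allele, sim$outcome$effect_allele)
})

test_that("identical configurations reproduce byte-identical tables", {
  cfg <- sim_config(n_snps = 30, theta = 0.1, prop_invalid = 0.2, seed = 42)
  a <- simulate_gwas_pair(cfg)
  b <- simulate_gwas_pair(cfg)
  expect_identical(a$exposure, b$exposure)
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$truth, b$truth)
})

test_that("reported standard errors follow the allele-frequency law exactly", {
  sim <- simulate_gwas_pair(sim_config(n_snps = 25, n_exposure = 12345,
                                       seed = 3))
  expect_equal(sim$exposure$standard_error,
               1 / sqrt(2 * sim$exposure$effect_allele_frequency *
                          (1 - sim$exposure$effect_allele_frequency) * 12345))
})

test_that("reported betas cover the true effects at the nominal 95% rate", {
  hits <- unlist(lapply(1:100, function(r) {
    sim <- simulate_gwas_pair(sim_config(n_snps = 100, seed = r))
    abs(sim$exposure$beta - sim$truth$gamma) <=
      1.96 * sim$exposure$standard_error
  }))
  expect_gt(mean(hits), 0.94)
  expect_lt(mean(hits), 0.96)
})

test_that("a null causal effect yields an IVW estimate within 3 SE of zero", {
  sim <- simulate_gwas_pair(sim_config(n_snps = 200, theta = 0,
                                       n_exposure = 1e6, n_outcome = 1e6,
                                       seed = 19))
  h <- harmonize(sim$exposure, sim$outcome, outcome_p_threshold = NULL)
  fit <- mr_ivw(h)
  expect_lt(abs(fit$beta), 3 * fit$se)
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(sim_config(prop_invalid = 1.5), "prop_invalid",
               class = "mrtriad_config_error")
  expect_error(sim_config(n_exposure = 1), "n_exposure",
               class = "mrtriad_config_error")
  expect_error(sim_config(sigma_gamma = 0), "sigma_gamma",
               class = "mrtriad_config_error")
  expect_error(sim_config(maf_range = c(0.3, 0.6)), "maf_range",
               class = "mrtriad_config_error")
})

test_that("mediation triangles encode the implied truth by construction", {
  cfg <- sim_config(n_snps = 20, n_mediator_snps = 15, theta1 = 0.2,
                    theta2 = 0.3, theta_direct = 0.14, seed = 8)
  tri <- simulate_mediation_triangle(cfg)
  expect_equal(tri$truth$theta_total[1], 0.2)
  expect_equal(tri$truth$true_proportion_pct[1], 30)
  expect_equal(sum(tri$truth$instrument_set == "mediator_instrument"), 15)
  # mediator-specific instruments are null on the exposure
  expect_true(all(tri$truth$gamma[tri$truth$instrument_set ==
                                    "mediator_instrument"] == 0))

  # theta1 = 0: nothing is mediated
  tri0 <- simulate_mediation_triangle(
    sim_config(n_snps = 10, theta1 = 0, theta2 = 0.3, theta_direct = 0.14,
               seed = 8))
  expect_equal(tri0$truth$true_proportion_pct[1], 0)

  # zero implied total effect: proportion undefined
  expect_error(simulate_mediation_triangle(
    sim_config(n_snps = 10, theta1 = 0.2, theta2 = 0.3,
               theta_direct = -0.06, seed = 8)),
    class = "mrtriad_config_error")
  # triangle parameters must be set
  expect_error(simulate_mediation_triangle(sim_config(n_snps = 10)),
               "theta1", class = "mrtriad_config_error")
})

test_that("the significance filter survivor count matches its analytic expectation", {
  # survivors among n variants at threshold q: each passes when
  # |lambda + Z| > z_q with lambda = gamma/se, so the expected count is
  # E[pnorm(-z_q + lambda) + pnorm(-z_q - lambda)] over the generator's
  # gamma and maf draws; estimate that expectation directly from fresh draws.
  thr <- 1e-5
  z_q <- stats::qnorm(1 - thr / 2)
  counts <- vapply(1:60, function(r) {
    sim <- simulate_gwas_pair(sim_config(n_snps = 2000, seed = 1000 + r))
    nrow(filter_significant(sim$exposure, thr))
  }, numeric(1))
  set.seed(99)
  maf <- runif(2e5, 0.05, 0.5)
  lambda <- abs(rnorm(2e5, 0, 0.1)) * sqrt(2 * maf * (1 - maf) * 3757)
  expected <- 2000 * mean(pnorm(-z_q + lambda) + pnorm(-z_q - lambda))
  expect_lt(abs(mean(counts) - expected) / expected, 0.03)
})
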