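test_that("the Wald ratio and its delta-method SE follow the closed form", {
  h <- make_h(0.5, 0.05, se_exp = 0.001, se_out = 0.01)
  fit <- mr_wald_ratio(h)
  expect_equal(fit$beta, 0.1)
  expect_equal(fit$se, 0.02)
  expect_equal(fit$or, exp(0.1))

  null <- mr_wald_ratio(make_h(0.5, 0, se_out = 0.01))
  expect_equal(null$beta, 0)
  expect_equal(null$p_value, 1)

  expect_error(mr_wald_ratio(make_h(0, 0.1)),
               class = "mrtriad_degenerate_instrument_error")
  expect_error(mr_wald_ratio(make_h(c(1, 1), c(1, 1))),
               class = "mrtriad_insufficient_instruments_error")
})

test_that("the first-order Wald SE matches a Monte-Carlo ratio-variance oracle", {
  # with negligible exposure noise, sd(by*/bx*) -> se_out/|bx|
  set.seed(21)
  bx <- 0.5; by <- 0.05; sy <- 0.01
  draws <- rnorm(1e6, by, sy) / rnorm(1e6, bx, 1e-4)
  expect_lt(abs(sd(draws) - 0.02) / 0.02, 0.01)
})

test_that("IVW reduces to the common ratio with zero heterogeneity", {
  h <- make_h(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3) * 1.7, se_out = 0.01)
  re <- mr_ivw(h, "random")
  fe <- mr_ivw(h, "fixed")
  expect_equal(re$beta, 1.7)
  expect_equal(attr(re, "q")$q, 0)
  expect_equal(re$se, fe$se)  # random-effects scaling floors at 1
})

test_that("IVW matches a normal-equations weighted regression through the origin", {
  h <- make_h(c(0.1, 0.2, 0.3), c(0.02, 0.04, 0.09), se_out = 0.01)
  fit <- mr_ivw(h, "random")
  orc <- oracle_ivw(h$beta_exp, h$beta_out, h$se_out)
  expect_equal(fit$beta, orc$beta, tolerance = 1e-12)
  expect_equal(fit$se, orc$se_random, tolerance = 1e-12)
  expect_equal(attr(fit, "q")$q, orc$q, tolerance = 1e-12)
})

test_that("Egger recovers an exact affine relationship and matches its oracle", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_h(bx, 0.03 + 1.4 * bx, se_out = 0.01)
  fit <- mr_egger(h)
  expect_equal(fit$beta, 1.4, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.03, tolerance = 1e-10)
  expect_lt(attr(fit, "q")$q, 1e-18)

  set.seed(4)
  h2 <- make_h(rnorm(6, 0.2, 0.1), rnorm(6, 0.05, 0.03),
               se_out = runif(6, 0.005, 0.02))
  fit2 <- mr_egger(h2)
  orc <- oracle_egger(h2$beta_exp, h2$beta_out, h2$se_out)
  expect_equal(fit2$beta, orc$slope, tolerance = 1e-12)
  expect_equal(fit2$intercept, orc$intercept, tolerance = 1e-12)
  expect_equal(fit2$se, orc$se_slope, tolerance = 1e-12)
  expect_equal(fit2$intercept_se, orc$se_intercept, tolerance = 1e-12)
  expect_equal(fit2$intercept_p,
               2 * pt(-abs(orc$intercept / orc$se_intercept), df = 4),
               tolerance = 1e-12)
})

test_that("the weighted median interpolates the cumulative weights at one half", {
  # equal weights: plain median
  h <- make_h(c(1, 1, 1), c(1, 2, 3), se_out = 1)
  expect_equal(mr_weighted_median(h, n_boot = 0)$beta, 2)
  # dominant weight pulls the estimate to its ratio:
  # sorted ratios {1, 2, 5}, weights {.01, .01, .98} give cumulative
  # standardized weights {.005, .015, .51}; interpolation at 0.5 lands at
  # 2 + 3 * (0.5 - 0.015) / (0.51 - 0.015)
  h2 <- make_h(c(1, 1, 1), c(5, 1, 2),
               se_out = 1 / sqrt(c(0.98, 0.01, 0.01)))
  expect_equal(mr_weighted_median(h2, n_boot = 0)$beta,
               2 + 3 * 0.485 / 0.495, tolerance = 1e-12)
})

test_that("mode estimators find the majority cluster and match a dense-grid oracle", {
  h <- make_h(rep(1, 4), c(0.2, 0.2, 0.2, 0.9), se_out = 0.05)
  # the minority ratio tilts the density slightly; the mode stays at the
  # majority cluster, not at the mean (0.375)
  expect_equal(mr_mode(h, weighted = FALSE, n_boot = 0)$beta, 0.2,
               tolerance = 0.05)

  # all ratios identical: degenerate bandwidth returns the common value
  h_id <- make_h(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12), se_out = 0.01)
  expect_equal(mr_mode(h_id, n_boot = 0)$beta, 0.3)

  # 20-variant cluster structure vs a 1e5-point brute-force density argmax
  set.seed(17)
  theta <- c(rnorm(14, 0.25, 0.02), rnorm(6, 0.8, 0.05))
  h3 <- make_h(rep(1, 20), theta, se_out = runif(20, 0.01, 0.05))
  for (weighted in c(TRUE, FALSE)) {
    fit <- mr_mode(h3, weighted = weighted, n_boot = 0)
    w <- if (weighted) 1 / h3$se_out^2 else rep(1, 20)
    k <- 20
    bw <- 0.9 * min(sd(theta), mad(theta)) * k^(-1 / 5)
    orc <- oracle_mode(theta, w, bw)
    expect_lt(abs(fit$beta - orc), 2 * diff(range(theta)) / 511)
  }
})

test_that("bootstrap SEs are seeded and reproducible", {
  set.seed(1)
  h <- make_h(rnorm(10, 0.2, 0.05), rnorm(10, 0.06, 0.02))
  a <- mr_weighted_median(h, n_boot = 200, seed = 7)
  b <- mr_weighted_median(h, n_boot = 200, seed = 7)
  expect_identical(a, b)
  expect_equal(a$seed, 7L)
  expect_true(is.finite(a$se) && a$se > 0)
})

test_that("estimators are sign- and scale-equivariant", {
  for (seed in 1:5) {
    set.seed(seed)
    h <- make_h(rnorm(12, 0.2, 0.05), rnorm(12, 0.05, 0.03),
                se_exp = 0.01, se_out = runif(12, 0.005, 0.02))
    fits <- function(hh) c(
      ivw = mr_ivw(hh)$beta, egger = mr_egger(hh)$beta,
      wm = mr_weighted_median(hh, n_boot = 0)$beta,
      sm = mr_mode(hh, weighted = FALSE, n_boot = 0)$beta,
      wmode = mr_mode(hh, weighted = TRUE, n_boot = 0)$beta)
    base <- fits(h)

    neg <- h; neg$beta_out <- -neg$beta_out
    expect_equal(fits(neg), -base, tolerance = 1e-8)
    expect_equal(mr_ivw(neg)$se, mr_ivw(h)$se)
    expect_equal(mr_egger(neg)$se, mr_egger(h)$se)

    sc <- h; sc$beta_exp <- 3 * sc$beta_exp; sc$se_exp <- 3 * sc$se_exp
    expect_equal(fits(sc), base / 3, tolerance = 1e-8)
  }
})

test_that("the fixed-effect IVW SE never exceeds the random-effects SE", {
  for (seed in 1:10) {
    set.seed(seed)
    h <- make_h(rnorm(8, 0.2, 0.05), rnorm(8, 0.05, 0.05), se_out = 0.01)
    expect_lte(mr_ivw(h, "fixed")$se, mr_ivw(h, "random")$se)
  }
})

test_that("the estimator panel reports all methods with coherent OR intervals", {
  set.seed(3)
  sim <- simulate_gwas_pair(sim_config(n_snps = 20, theta = 0.15,
                                       n_exposure = 5e4, n_outcome = 5e4,
                                       seed = 3))
  h <- harmonize(sim$exposure, sim$outcome, outcome_p_threshold = NULL)
  res <- mr_all(h, n_boot = 100, seed = 1)
  expect_setequal(res$method, c("ivw_re", "egger", "weighted_median",
                                "simple_mode", "weighted_mode"))
  expect_equal(res$or, exp(res$beta))
  expect_true(all(res$ci_low < res$or & res$or < res$ci_high))
  expect_equal(unique(res$exposure), "exposure")
  # minimum instrument counts
  expect_error(mr_ivw(make_h(1, 1)),
               class = "mrtriad_insufficient_instruments_error")
  expect_error(mr_egger(make_h(c(1, 1), c(1, 1))),
               class = "mrtriad_insufficient_instruments_error")
})
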