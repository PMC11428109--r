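test_that("significance filtering uses a strict inequality", {
  s <- make_sumstats(3, p = c(1e-6, 1e-5, 1e-4))
  kept <- filter_significant(s, 1e-5)
  expect_equal(kept$variant_id, "rs001")
  expect_equal(nrow(filter_significant(s, 1)), 3)  # all rows have p < 1
})

test_that("F-statistic screening is strict and commutes with significance filtering", {
  s <- make_sumstats(3, beta = c(0.1, 0.03, 0.05),
                     se = rep(0.01, 3), p = c(1e-8, 1e-7, 1e-6))
  f <- add_f_statistic(s)
  expect_equal(f$f_statistic, c(100, 9, 25))
  kept <- filter_fstat(s, 10)
  expect_equal(kept$variant_id, c("rs001", "rs003"))  # F = 9 dropped
  # strictness at the boundary: a variant whose F equals the cutoff exactly
  # is dropped
  expect_equal(filter_fstat(s, f_min = f$f_statistic[3])$variant_id, "rs001")

  a <- filter_fstat(filter_significant(s, 1e-6), 10)
  b <- filter_significant(filter_fstat(s, 10), 1e-6)
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("distance-only clumping keeps the most significant variant per window", {
  s <- make_sumstats(2, p = c(1e-8, 1e-6), pos = c(1e6, 1e6 + 5000 * 1000))
  expect_equal(ld_clump(s, clump_window_kb = 10000)$variant_id, "rs001")
  far <- make_sumstats(2, p = c(1e-8, 1e-6), pos = c(1e6, 1e6 + 20000 * 1000))
  expect_equal(nrow(ld_clump(far, clump_window_kb = 10000)), 2)
})

test_that("an LD matrix rescues in-window variants below the r2 threshold", {
  s <- make_sumstats(2, p = c(1e-8, 1e-6), pos = c(1e6, 1e6 + 5000 * 1000))
  ld_hi <- matrix(c(1, 0.5, 0.5, 1), 2,
                  dimnames = list(s$variant_id, s$variant_id))
  expect_equal(ld_clump(s, r2_threshold = 0.001, ld = ld_hi)$variant_id,
               "rs001")
  ld_lo <- matrix(c(1, 1e-4, 1e-4, 1), 2,
                  dimnames = list(s$variant_id, s$variant_id))
  expect_equal(nrow(ld_clump(s, r2_threshold = 0.001, ld = ld_lo)), 2)
  expect_error(ld_clump(s, ld = matrix(1, 1, 1, dimnames = list("rs001", "rs001"))),
               class = "mrtriad_ld_error")
  expect_error(ld_clump(s, ld = unname(ld_lo)), class = "mrtriad_ld_error")
})

test_that("greedy clumping matches a selection-and-removal oracle on block LD", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 100
    s <- make_sumstats(n, p = runif(n, 1e-10, 1e-4),
                       pos = sort(sample(1:5e7, n)))  # dense: windows overlap
    ld <- make_block_ld(s$variant_id, block_size = 10, rho = 0.9)
    kept <- ld_clump(s, r2_threshold = 0.01, clump_window_kb = 10000, ld = ld)
    expect_equal(sort(kept$variant_id),
                 oracle_clump(s, 0.01, 10000, ld))
    # post-hoc invariant: no two kept variants violate the window + r2 rule
    for (i in seq_len(nrow(kept))) {
      for (j in seq_len(nrow(kept))) {
        if (i < j) {
          within <- abs(kept$base_pair_location[i] -
                          kept$base_pair_location[j]) <= 1e7
          expect_false(within &&
                         ld[kept$variant_id[i], kept$variant_id[j]] >= 0.01)
        }
      }
    }
  }
})

test_that("harmonization aligns swapped alleles and drops mismatches and palindromes", {
  exp <- make_sumstats(4, ea = c("A", "A", "A", "C"),
                       oa = c("G", "T", "G", "T"),
                       beta = c(0.1, 0.1, 0.1, 0.1))
  out <- make_sumstats(4, ea = c("G", "A", "C", "C"),
                       oa = c("A", "T", "T", "T"),
                       beta = c(0.2, 0.2, 0.2, 0.2),
                       p = rep(0.5, 4), trait_id = "outcome")
  h <- harmonize(exp, out, outcome_p_threshold = NULL)
  # rs001: swapped alleles -> sign flip; rs002: palindromic -> dropped;
  # rs003: A/G vs C/T mismatch -> dropped; rs004: aligned -> untouched
  expect_equal(h$variant_id, c("rs001", "rs004"))
  expect_equal(h$beta_out, c(-0.2, 0.2))
  expect_true(h$sign_flipped[1])
  drops <- attr(h, "drops")
  expect_equal(drops$reason[drops$variant_id == "rs002"], "palindromic")
  expect_equal(drops$reason[drops$variant_id == "rs003"], "allele_mismatch")
})

test_that("variants directly associated with the outcome are excluded", {
  exp <- make_sumstats(3)
  out <- make_sumstats(3, p = c(1e-6, 1e-5, 0.5), trait_id = "outcome")
  h <- harmonize(exp, out, outcome_p_threshold = 1e-5)
  expect_equal(h$variant_id, c("rs002", "rs003"))  # strict: p = 1e-5 kept
  expect_equal(nrow(harmonize(exp, out, outcome_p_threshold = NULL)), 3)
})

test_that("harmonization is idempotent and errors on empty intersections", {
  sim <- simulate_gwas_pair(sim_config(n_snps = 30, theta = 0.1,
                                       palindrome_fraction = 0.2, seed = 2))
  h1 <- harmonize(sim$exposure, sim$outcome, outcome_p_threshold = NULL)
  # rebuild sumstats from the harmonized output and harmonize again
  rebuild <- function(h, side) {
    sumstats(tibble::tibble(
      variant_id = h$variant_id, chromosome = h$chromosome,
      base_pair_location = h$base_pair_location,
      effect_allele = h$effect_allele, other_allele = h$other_allele,
      effect_allele_frequency = h[[paste0("eaf_", side)]],
      beta = h[[paste0("beta_", side)]],
      standard_error = h[[paste0("se_", side)]],
      p_value = h[[paste0("p_", side)]], n = 1000),
      trait_id = side, quiet = TRUE)
  }
  h2 <- harmonize(rebuild(h1, "exp"), rebuild(h1, "out"),
                  outcome_p_threshold = NULL)
  cols <- c("variant_id", "beta_exp", "se_exp", "beta_out", "se_out")
  expect_equal(tibble::as_tibble(h2)[cols], tibble::as_tibble(h1)[cols],
               ignore_attr = TRUE)
  expect_false(any(h2$sign_flipped))

  other <- make_sumstats(2, trait_id = "unrelated")
  other$variant_id <- c("rs901", "rs902")
  expect_error(harmonize(sim$exposure, sumstats(other, trait_id = "unrelated",
                                                quiet = TRUE)),
               "unrelated", class = "mrtriad_empty_harmonization_error")
})

test_that("palindrome rescue retains frequency-resolvable ambiguous variants", {
  exp <- make_sumstats(2, ea = c("A", "A"), oa = c("T", "T"))
  exp$effect_allele_frequency <- c(0.1, 0.48)
  out <- make_sumstats(2, ea = c("A", "A"), oa = c("T", "T"),
                       beta = c(0.2, 0.2), p = rep(0.5, 2),
                       trait_id = "outcome")
  out$effect_allele_frequency <- c(0.9, 0.1)  # first is strand-discordant
  expect_equal(nrow(harmonize(exp, out, outcome_p_threshold = NULL)), 0)
  h <- harmonize(exp, out, outcome_p_threshold = NULL,
                 palindrome_rescue = TRUE)
  expect_equal(h$variant_id, "rs001")  # rs002 too close to 0.5 to resolve
  expect_equal(h$beta_out, -0.2)       # aligned by flipping frequency side
})

test_that("the selection pipeline logs per-stage counts", {
  sim <- simulate_gwas_pair(sim_config(n_snps = 200, n_exposure = 2e4,
                                       position_gap_kb = 5000, seed = 7))
  inst <- select_instruments(sim$exposure, selection_config())
  log <- attr(inst, "selection_log")
  expect_equal(log$stage, c("significance", "ld_clump", "f_statistic"))
  expect_equal(log$n_in[1], 200)
  expect_equal(log$n_in - log$n_dropped, c(log$n_in[-1], nrow(inst)))
  expect_true(all(inst$p_value < 1e-5))
})
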