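# Fixture builders and independent oracles used across the suite.

# Harmonized-data fixture from raw beta/se vectors.
make_h <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.01,
                   ids = sprintf("rs%03d", seq_along(beta_exp))) {
  k <- length(beta_exp)
  tibble::tibble(
    variant_id = ids,
    beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
    beta_out = beta_out, se_out = rep_len(se_out, k))
}

# Small well-formed sumstats fixture.
make_sumstats <- function(n = 3, p = 10^-(seq_len(n) + 3),
                          ea = rep("A", n), oa = rep("G", n),
                          pos = seq_len(n) * 1e6, chrom = "1",
                          beta = rep(0.1, n), se = rep(0.01, n),
                          trait_id = "trait") {
  sumstats(tibble::tibble(
    variant_id = sprintf("rs%03d", seq_len(n)), chromosome = chrom,
    base_pair_location = pos, effect_allele = ea, other_allele = oa,
    effect_allele_frequency = 0.3, beta = beta, standard_error = se,
    p_value = p, n = 1000), trait_id = trait_id, quiet = TRUE)
}

# Weighted least squares through the origin by explicit normal equations.
oracle_ivw <- function(bx, by, sy) {
  w <- 1 / sy^2
  X <- matrix(bx, ncol = 1)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * by))
  se_fixed <- sqrt(solve(t(X) %*% (w * X))[1, 1])
  q <- sum(w * (by - beta[1] * bx)^2)
  k <- length(bx)
  list(beta = beta[1], se_fixed = se_fixed, q = q,
       se_random = se_fixed * max(1, sqrt(q / (k - 1))))
}

# Weighted least squares with intercept by explicit normal equations,
# on data oriented so every exposure beta is non-negative.
oracle_egger <- function(bx, by, sy) {
  flip <- ifelse(bx < 0, -1, 1)
  bx <- bx * flip; by <- by * flip
  w <- 1 / sy^2
  X <- cbind(1, bx)
  XtWX <- t(X) %*% (w * X)
  coefs <- solve(XtWX, t(X) %*% (w * by))
  resid <- by - X %*% coefs
  q <- sum(w * resid^2)
  k <- length(bx)
  scale <- max(1, sqrt(q / (k - 2)))
  ses <- sqrt(diag(solve(XtWX))) * scale
  list(intercept = unname(coefs[1]), slope = unname(coefs[2]),
       se_intercept = unname(ses[1]), se_slope = unname(ses[2]), q = q)
}

# Clumping by repeated selection-and-removal (different mechanics from the
# package's skip-if-blocked greedy pass; must give the same kept set).
oracle_clump <- function(stats, r2_threshold, clump_window_kb, ld = NULL) {
  remaining <- stats[order(stats$p_value, stats$variant_id), , drop = FALSE]
  kept <- character(0)
  window_bp <- clump_window_kb * 1000
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    kept <- c(kept, top$variant_id)
    conflict <- remaining$chromosome == top$chromosome &
      abs(remaining$base_pair_location - top$base_pair_location) <= window_bp
    if (!is.null(ld)) {
      conflict <- conflict &
        ld[remaining$variant_id, top$variant_id] >= r2_threshold
    }
    conflict[1] <- TRUE
    remaining <- remaining[!conflict, , drop = FALSE]
  }
  sort(kept)
}

# Kernel-density mode over a dense grid (1e5 points).
oracle_mode <- function(theta, w, h_bw, n_grid = 1e5) {
  w <- w / sum(w)
  grid <- seq(min(theta), max(theta), length.out = n_grid)
  dens <- colSums(w * outer(theta, grid, function(t, x)
    stats::dnorm(x, t, h_bw)))
  grid[which.max(dens)]
}

# Block-diagonal AR(1) LD matrix for clumping tests.
make_block_ld <- function(ids, block_size = 10, rho = 0.9) {
  n <- length(ids)
  ld <- matrix(0, n, n, dimnames = list(ids, ids))
  for (start in seq(1, n, by = block_size)) {
    idx <- start:min(start + block_size - 1, n)
    ld[idx, idx] <- rho^abs(outer(idx, idx, `-`))
  }
  diag(ld) <- 1
  ld
}
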