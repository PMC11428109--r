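---
title: "Methods: two-sample MR, sensitivity analysis, and two-step mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, sensitivity analysis, and two-step mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtriad)
```

This vignette documents the statistical model behind `mrtriad`, the defaults
and why they were chosen, the design of the synthetic generator (including
where it deviates from a literal textbook model and why), and the numerical
decisions that affect results at the margins.

## 1. The causal model

For a variant $j$ with effect $\gamma_j$ on the exposure $X$, the two-sample
MR model for the outcome association is

$$\beta_{Yj} = \theta\,\gamma_j + \alpha_j + \varepsilon_j,$$

where $\theta$ is the causal effect of $X$ on $Y$ on the log-odds scale,
$\alpha_j$ is a direct (pleiotropic) effect that is zero for valid
instruments, and $\varepsilon_j$ is estimation noise with standard error
$se_{Yj}$. Each stage of the package operationalizes one part of this model:

1. **Instrument selection** (`select_instruments()`): keep variants with
   exposure $p <$ threshold, prune them to approximate independence by greedy
   LD clumping, and drop weak instruments by the per-variant F-statistic
   $F_j = (\hat\beta_{Xj}/se_{Xj})^2$.
2. **Harmonization** (`harmonize()`): align effect alleles across the two
   studies, flipping signs for swapped alleles, dropping allele mismatches
   and strand-ambiguous (palindromic) pairs, and optionally excluding
   variants directly associated with the outcome.
3. **Estimation** (`mr_ivw()`, `mr_egger()`, `mr_weighted_median()`,
   `mr_mode()`, or the `mr_all()` panel): combine per-variant Wald ratios
   $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ under different validity
   assumptions.
4. **Sensitivity** (`sensitivity_report()`): Cochran's Q, the Egger
   intercept, an MR-PRESSO-style global/outlier/distortion analysis, and
   leave-one-out IVW.
5. **Mediation** (`two_step_mediation()`, `mediation_screen()`): combine
   three MR legs into a mediated effect and proportion mediated.
6. **Pipeline** (`run_config()` + `run_all()`): forward screening with
   Benjamini–Hochberg FDR, reverse-direction MR filtering, mediator
   screening, and reproducible TSV/YAML outputs.

### Estimators

With ratio-scale weights $w_j = \hat\beta_{Xj}^2/se_{Yj}^2$:

- **IVW** is the weighted regression of $\hat\beta_Y$ on $\hat\beta_X$
  through the origin. The fixed-effect SE is
  $(\sum_j w_j \hat\beta_{Xj}^2 / \hat\beta_{Xj}^2)^{-1/2}$ rewritten in
  regression form; the multiplicative random-effects model
  (`model = "random"`, the default) scales it by
  $\max\!\big(1, \sqrt{Q/(k-1)}\big)$, so the random-effects SE can never be
  smaller than the fixed-effect SE.
- **MR-Egger** is the same regression with an intercept, after orienting
  every variant so $\hat\beta_X \ge 0$ (the model is not sign-invariant;
  orientation makes the intercept interpretable as average directional
  pleiotropy). SEs are scaled by $\max(1, \sqrt{Q_E/(k-2)})$ and p-values
  use a $t$ distribution with $k-2$ degrees of freedom, which is the
  conventional small-sample correction for the two estimated coefficients.
- **Weighted median**: sort ratios $\hat\theta_{(1)} \le \dots \le
  \hat\theta_{(k)}$ and compute standardized cumulative weights
  $s_j = (\sum_{i\le j} w_i - w_j/2)/\sum_i w_i$; the estimate linearly
  interpolates between the two ratios bracketing $s = 0.5$. Its SE comes
  from a seeded parametric bootstrap.
- **Simple/weighted mode**: the ratios are smoothed with a normal kernel of
  bandwidth $h = \phi \cdot 0.9\,\min(\mathrm{sd}, \mathrm{mad})\,k^{-1/5}$
  and the estimate is the density argmax; the weighted variant weights each
  kernel by $w_j$. Bootstrap SE as for the median.
- With one instrument only the **Wald ratio** (first-order delta SE
  $se_Y/|\hat\beta_X|$) is available; with two, only IVW. `mr_all()` applies
  this escalation automatically.

### MR-PRESSO-style outlier analysis

`mr_presso()` computes, for each variant $j$, the IVW slope with $j$ removed,
and the observed global residual sum of squares
$\mathrm{RSS} = \sum_j (\hat\beta_{Yj} - \hat\theta_{(-j)}\hat\beta_{Xj})^2$
(unweighted residuals against leave-one-out slopes). The null distribution
comes from `n_sim` parametric simulations of outcome betas around the
leave-one-out fitted values; the empirical p-value uses the standard
add-one correction $(1+b)/(1+\texttt{n\_sim})$, so the smallest attainable
p is $1/(1+\texttt{n\_sim})$ — with the default `n_sim = 1000` the floor is
about 0.001. Per-variant outlier p-values are Bonferroni-adjusted by $k$;
consequently an outlier can only be declared when
$k/(\texttt{n\_sim}+1) < \alpha$, which is why small `n_sim` with large $k$
is rejected in practice by yielding no outliers rather than spurious ones.
If outliers are found, the distortion test compares the outlier-corrected
slope with slopes after removing equally many random variants. Rows are
sorted by `variant_id` before simulation so results are invariant to input
row order given the same seed.

### Two-step mediation

Given legs $\hat\beta_1$ (exposure→mediator), $\hat\beta_2$
(mediator→outcome), and $\hat\beta_3$ (exposure→outcome total effect):

$$\hat\beta_{med} = \hat\beta_1\hat\beta_2,\qquad
  se_{med} = \sqrt{\hat\beta_1^2 se_2^2 + \hat\beta_2^2 se_1^2},\qquad
  \hat R = 100\,\hat\beta_1\hat\beta_2/\hat\beta_3.$$

The proportion is deliberately **not clamped** to $[0, 100]$: negative or
\>100% proportions are informative (sign-discordant paths, near-zero total
effects) and are common in applied work. Instead, the result carries an
`unstable_proportion` flag set when $|\hat\beta_3| < 2\,se_3$, i.e. when the
denominator is statistically indistinguishable from zero and the ratio should
not be trusted. An optional seeded parametric bootstrap
(`boot_ci = TRUE`) gives percentile intervals for $\hat R$, which are more
honest than delta intervals when the denominator is noisy.

## 2. Defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| exposure p threshold | `1e-5` | conventional relaxed threshold for molecular/cellular exposures where genome-wide hits are scarce; strict `<` |
| reverse-direction p threshold | `5e-8` | genome-wide significance for the reverse leg, where false reverse signals are costlier than missed ones |
| clumping window | 10,000 kb | generous single-locus window; with no LD matrix the window alone defines independence (distance-only fallback) |
| clumping r² | 0.001 | near-independence; only consulted when an LD matrix is supplied |
| F minimum | 10 | the standard weak-instrument rule of thumb; strict `>` so F = 10 exactly is excluded |
| `outcome_p_threshold` (harmonization) | `1e-5` | removes instruments directly associated with the outcome — a pleiotropy guard |
| palindrome handling | drop; optional EAF rescue at $|EAF-0.5| > 0.08$ | dropping is the safe default; rescue is off because allele frequencies may differ across ancestries |
| IVW model | multiplicative random effects | robust default under unmodelled heterogeneity; coincides with fixed effects when $Q \le k-1$ |
| `n_boot` | 1000 | bootstrap SE Monte-Carlo error well below reported precision |
| `n_sim` (PRESSO) | 1000 | empirical-p floor ≈ 0.001; outlier detection feasible for $k \lesssim 50$ at $\alpha = 0.05$ |

One default deserves emphasis: in the **forward** direction the pipeline sets
`outcome_p_threshold = NULL` (see `run_config()`). When a true causal effect
exists, every good instrument is associated with the outcome *through the
exposure*, so the outcome-association guard would systematically delete the
best instruments and bias screening toward the null. In the **reverse**
direction the guard is kept at `1e-5`: there it removes instruments shared
with the original exposure, which would otherwise produce false
reverse-causation flags.

## 3. The synthetic generator

`simulate_gwas_pair()` produces summary-level statistics directly rather than
simulating individual genotypes:

- minor allele frequencies uniform on `maf_range` (default 0.05–0.5);
- standard errors from the asymptotic regression formula
  $se = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,N}$;
- observed betas drawn as true value + $N(0, se^2)$ noise, independently in
  the exposure and outcome samples (a genuinely two-sample design with no
  sample overlap);
- two-sided normal p-values, floored at the smallest positive double so that
  downstream `log`/ranking never meets a literal zero;
- an exact number `round(prop_invalid * n)` of invalid instruments with
  pleiotropic effects $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$, and an
  exact number of palindromic variants, so tests can make deterministic
  count assertions;
- variant positions on one synthetic chromosome spaced `position_gap_kb`
  apart (default 20,000 kb), i.e. outside the default clumping window, so
  LD pruning is exercised but does not silently change instrument counts
  unless a test asks it to. Positions are stored as doubles because realistic
  spacing times realistic counts overflows 32-bit integers.

**True effect orientation.** Per-variant exposure effects are drawn as
$\gamma_j = |N(0, \sigma_\gamma^2)|$ — half-normal — and the effect allele is
defined as the exposure-increasing allele. This is a deliberate design
choice. With symmetric $\gamma_j$ and alleles labelled arbitrarily, the
"direction" of a pleiotropic effect relative to the instrument orientation is
random, and *directional* pleiotropy (a non-zero mean $\mu_\alpha$) cancels
in aggregate: the Egger intercept would be inestimable by construction and
IVW would show no directional bias no matter how large $\mu_\alpha$ is. Real
directional pleiotropy is defined relative to the exposure-increasing allele,
which is exactly what the half-normal draw encodes. The magnitude
distribution is otherwise unchanged.

**Realism and limits.** The generator reproduces the features that matter
for method behavior — weight heterogeneity via MAF-dependent SEs, weak
instruments, invalid instruments with directional or balanced pleiotropy,
palindromic alleles, two-sample independence — but it is not a population
genetics simulator: there is no LD structure beyond what a supplied LD matrix
injects into clumping tests, no winner's curse (instruments are selected in
the same sample they are estimated in, which mildly inflates F-statistics),
no allele-frequency mismatch between studies unless constructed by hand, and
binary-trait effects are treated on a continuous log-odds scale with
linear-regression SEs rather than logistic ones.

`simulate_mediation_triangle()` builds exposure→mediator→outcome systems:
exposure instruments affect the mediator through $\theta_1$, an independent
set of mediator-specific instruments affects the mediator directly, and the
outcome receives $\theta_2 \times$ (mediator genetic value) plus a direct
exposure path $\theta_\mathrm{direct}$, giving a known true proportion
mediated $100\,\theta_1\theta_2/(\theta_1\theta_2 + \theta_\mathrm{direct})$.
One known bias is left in intentionally because it mirrors applied practice:
mediator instruments selected at a relaxed threshold can include variants
whose mediator association is inherited from the exposure, which slightly
inflates the mediator→outcome leg and hence the estimated proportion (the
validation suite observes ≈32.5% against a design value of 30%).

## 4. Numerical decisions

- **Mode bandwidth fallback.** $0.9\min(\mathrm{sd},\mathrm{mad})k^{-1/5}$
  degenerates when ties make the MAD zero. The implementation takes the
  minimum over the *positive* members of $\{\mathrm{sd}, \mathrm{mad}\}$ and
  returns the common ratio outright only when both are zero (all ratios
  identical). The density is evaluated at the $k$ ratio points plus a
  512-point grid over their range, so the argmax can never miss a spike at a
  data point.
- **Tie-breaking.** Clumping processes variants by ascending p-value with
  lexicographic `variant_id` as tie-break, making kept sets deterministic.
- **Strict inequalities.** All thresholds (significance, F, outcome-p) are
  strict, and tests pin the boundary behavior.
- **Random-effects floor.** The $\max(1,\cdot)$ in both IVW and Egger SE
  scaling prevents under-dispersion from shrinking confidence intervals
  below their fixed-effect width.
- **Reproducibility.** Every stochastic routine (bootstrap SEs, PRESSO
  simulations, the generator) takes an explicit seed and records it in its
  output; `run_all()` writes byte-identical TSVs for identical
  configurations.

## 5. Validation problem sizes

The acceptance-level tests run the package on study conditions chosen (and
frozen before the tests were written) to make each statistical property
detectable with comfortable margins at feasible runtime:

- estimator consistency: 100 variants, $N = 10^5$, $\theta = 0.2$, 500
  replicates — all five estimators' mean within 0.02 of truth;
- Egger intercept recovery: 100% invalid instruments,
  $\mu_\alpha = 0.02$, $\sigma_\alpha = 0.01$;
- weighted-median robustness: 30% invalid, $\mu_\alpha = 0.1$, $N = 5\times
  10^5$ so that instrument noise does not mask the IVW bias being contrasted;
- PRESSO calibration/power: $k = 20$, `n_sim = 500` — small enough that the
  Bonferroni-adjusted outlier floor $k/(\texttt{n\_sim}+1)$ stays below 0.05;
- Cochran's Q law: $k = 10$, $\theta = 0$, 2000 replicates against
  $\chi^2_9$ by a Kolmogorov–Smirnov test;
- mediation recovery: 150 + 150 instruments at $N = 5\times 10^5$, median
  estimated proportion within 10 points of the design value of 30%.

These sizes are the package's own validation choices, not properties of any
particular dataset.

## 6. Known limitations

- Binary outcomes are handled on the log-odds scale throughout; no
  liability-scale conversion is provided.
- The LD-aware clumping path requires a caller-supplied dense r² matrix with
  named dimensions; there is no reference-panel interface.
- MR-PRESSO's distortion test requires at least one non-outlier left after
  correction and errors (with class
  `mrtriad_degenerate_correction_error`) when every variant is flagged.
- Bootstrap SEs for median/mode estimators assume approximate normality of
  the per-variant summary statistics.

```{r example, eval = FALSE}
# End-to-end run on a synthetic study:
cfg <- run_config(
  synthetic = list(
    n_exposures = 3, n_mediators = 2,
    theta_exposures = c(0.2, 0, 0), mediated_path = TRUE,
    config = sim_config(n_snps = 30, n_exposure = 1e5, n_mediator = 1e5,
                        n_outcome = 2e5, theta1 = 0.25, theta2 = 0.3,
                        theta_direct = 0.15, seed = 11)),
  out_dir = tempfile("mr_run"), seed = 11)
run_all(cfg)
```
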