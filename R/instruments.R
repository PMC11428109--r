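# Instrument selection and exposure-outcome harmonization:
# significance filtering, greedy LD clumping, F-statistic screening,
# allele alignment and palindromic-variant removal.

#' Instrument-selection configuration
#'
#' Thresholds governing instrument selection. The forward analysis
#' conventionally relaxes the exposure threshold to `1e-5`; the reverse
#' analysis uses genome-wide significance `5e-8`.
#'
#' @param p_threshold Exposure significance cutoff (strict `<`).
#' @param r2_threshold LD r-squared cutoff for clumping, in `(0, 1)`.
#' @param clump_window_kb Clumping window in kilobases.
#' @param f_min Per-variant F-statistic cutoff (strict `>`).
#' @param outcome_p_threshold Drop instruments whose outcome association has
#'   `p < outcome_p_threshold` during harmonization (directly
#'   outcome-associated variants); `NULL` disables the exclusion.
#' @return A list of class `"selection_config"`.
#' @export
selection_config <- function(p_threshold = 1e-5, r2_threshold = 0.001,
                             clump_window_kb = 10000, f_min = 10,
                             outcome_p_threshold = 1e-5) {
  stopifnot(p_threshold > 0, r2_threshold > 0, r2_threshold < 1,
            clump_window_kb > 0, f_min > 0)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 clump_window_kb = clump_window_kb, f_min = f_min,
                 outcome_p_threshold = outcome_p_threshold),
            class = "selection_config")
}

#' Keep variants passing a significance threshold
#'
#' Strict inequality: a variant with `p_value` exactly at the threshold is
#' excluded.
#'
#' @param stats A `sumstats` tibble.
#' @param p_threshold Significance cutoff.
#' @return The subset with `p_value < p_threshold` (possibly empty).
#' @export
filter_significant <- function(stats, p_threshold = 1e-5) {
  keep_attrs(dplyr::filter(stats, .data$p_value < p_threshold), stats)
}

#' Per-variant instrument-strength F-statistics
#'
#' The single-variant approximation `F = (beta / se)^2`.
#'
#' @param stats A `sumstats` tibble.
#' @return `stats` with an added `f_statistic` column.
#' @export
add_f_statistic <- function(stats) {
  keep_attrs(dplyr::mutate(stats,
                           f_statistic = (.data$beta / .data$standard_error)^2),
             stats)
}

#' Drop weak instruments by F-statistic
#'
#' Retains variants with `F > f_min` (strict: `F` exactly equal to the
#' cutoff is dropped).
#'
#' @inheritParams add_f_statistic
#' @param f_min Cutoff (conventionally 10).
#' @return Filtered `sumstats` tibble (without the `f_statistic` column).
#' @export
filter_fstat <- function(stats, f_min = 10) {
  keep_attrs(
    dplyr::filter(stats, (.data$beta / .data$standard_error)^2 > f_min),
    stats)
}

keep_attrs <- function(new, old) {
  attr(new, "trait_id") <- attr(old, "trait_id", exact = TRUE)
  attr(new, "trait_name") <- attr(old, "trait_name", exact = TRUE)
  if (!inherits(new, "sumstats")) class(new) <- c("sumstats", class(new))
  new
}

validate_ld_matrix <- function(ld, ids) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld) ||
      is.null(rownames(ld)) || is.null(colnames(ld)) ||
      !identical(rownames(ld), colnames(ld))) {
    rlang::abort("LD matrix must be square with identical row/column variant ids",
                 class = "mrtriad_ld_error")
  }
  if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8)) ||
      !isTRUE(all.equal(unname(diag(ld)), rep(1, nrow(ld)), tolerance = 1e-8))) {
    rlang::abort("LD matrix must be symmetric with unit diagonal",
                 class = "mrtriad_ld_error")
  }
  missing <- setdiff(ids, rownames(ld))
  if (length(missing) > 0) {
    rlang::abort(paste0("LD matrix does not cover variant(s): ",
                        paste(utils::head(missing, 5), collapse = ", ")),
                 class = "mrtriad_ld_error")
  }
  invisible(ld)
}

#' Greedy LD clumping of summary statistics
#'
#' Variants are visited in ascending p-value order (ties broken by
#' lexicographic `variant_id`). A variant is kept unless it lies within
#' `clump_window_kb` of an already-kept variant on the same chromosome
#' *and*, when an LD matrix is supplied, its r-squared with that kept
#' variant is at least `r2_threshold`. Without an LD matrix, distance alone
#' decides (a documented fallback for when no LD estimates are available).
#'
#' @param stats A `sumstats` tibble.
#' @param r2_threshold LD cutoff.
#' @param clump_window_kb Window in kb.
#' @param ld Optional square r-squared matrix with variant ids as dimnames,
#'   covering all variants in `stats`.
#' @return The retained subset, in the original row order.
#' @export
ld_clump <- function(stats, r2_threshold = 0.001, clump_window_kb = 10000,
                     ld = NULL) {
  if (nrow(stats) == 0) return(stats)
  if (!is.null(ld)) validate_ld_matrix(ld, stats$variant_id)
  ord <- order(stats$p_value, stats$variant_id)
  pos <- stats$base_pair_location
  chrom <- stats$chromosome
  window_bp <- clump_window_kb * 1000
  kept <- integer(0)
  for (i in ord) {
    blocked <- FALSE
    for (j in kept) {
      if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= window_bp) {
        if (is.null(ld) ||
            ld[stats$variant_id[i], stats$variant_id[j]] >= r2_threshold) {
          blocked <- TRUE
          break
        }
      }
    }
    if (!blocked) kept <- c(kept, i)
  }
  keep_attrs(stats[sort(kept), , drop = FALSE], stats)
}

#' Select instruments for one exposure
#'
#' Composes the selection pipeline: significance filter, LD clumping, and
#' F-statistic screen.
#'
#' @param stats Exposure `sumstats`.
#' @param config A [selection_config()].
#' @param ld Optional LD matrix (see [ld_clump()]).
#' @return Filtered `sumstats` tibble with attribute `selection_log`, a
#'   tibble of per-stage input/dropped counts.
#' @export
select_instruments <- function(stats, config = selection_config(), ld = NULL) {
  s1 <- filter_significant(stats, config$p_threshold)
  s2 <- ld_clump(s1, config$r2_threshold, config$clump_window_kb, ld)
  s3 <- filter_fstat(s2, config$f_min)
  log <- tibble::tibble(
    stage = c("significance", "ld_clump", "f_statistic"),
    n_in = c(nrow(stats), nrow(s1), nrow(s2)),
    n_dropped = c(nrow(stats) - nrow(s1), nrow(s1) - nrow(s2),
                  nrow(s2) - nrow(s3)))
  attr(s3, "selection_log") <- log
  s3
}

#' Identify strand-ambiguous (palindromic) allele pairs
#'
#' A/T and C/G variants cannot be strand-resolved from alleles alone.
#'
#' @param ea,oa Character vectors of effect and other alleles.
#' @return Logical vector.
#' @export
is_palindromic_pair <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

is_palindromic <- is_palindromic_pair

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins the two tables on `variant_id` and expresses both effects per
#' copy of the exposure's effect allele. Outcome records whose alleles are
#' swapped relative to the exposure have their beta sign flipped and
#' effect-allele frequency complemented; records whose alleles do not match
#' at all are dropped. Palindromic (A/T, C/G) variants cannot be strand-
#' resolved from alleles alone and are dropped unconditionally by default;
#' `palindrome_rescue = TRUE` instead retains those whose allele frequencies
#' are far from 0.5 on both sides (`|eaf - 0.5| > eaf_tolerance`), aligning
#' by frequency. Variants directly associated with the outcome
#' (`p < outcome_p_threshold`) are excluded unless the threshold is `NULL`.
#'
#' @param exposure,outcome `sumstats` tibbles.
#' @param outcome_p_threshold Outcome-association exclusion threshold
#'   (`NULL` disables).
#' @param palindrome_rescue Retain frequency-resolvable palindromic variants
#'   (off by default).
#' @param eaf_tolerance Minimum distance of both frequencies from 0.5 for a
#'   palindromic rescue.
#' @return A tibble of class `"mr_harmonized"` with columns `variant_id`,
#'   `chromosome`, `base_pair_location`, `effect_allele`, `other_allele`,
#'   `beta_exp`, `se_exp`, `p_exp`, `eaf_exp`, `beta_out`, `se_out`, `p_out`,
#'   `eaf_out`, `sign_flipped`; attributes `exposure_id`, `outcome_id` and
#'   `drops` (a tibble of dropped variant ids with reasons).
#' @export
harmonize <- function(exposure, outcome, outcome_p_threshold = 1e-5,
                      palindrome_rescue = FALSE, eaf_tolerance = 0.08) {
  exp_id <- trait_id(exposure)
  out_id <- trait_id(outcome)
  e <- tibble::as_tibble(exposure)
  o <- tibble::as_tibble(outcome)
  j <- dplyr::inner_join(
    dplyr::select(e, "variant_id", "chromosome", "base_pair_location",
                  "effect_allele", "other_allele",
                  beta_exp = "beta", se_exp = "standard_error",
                  p_exp = "p_value", eaf_exp = "effect_allele_frequency"),
    dplyr::select(o, "variant_id", ea_out = "effect_allele",
                  oa_out = "other_allele", beta_out = "beta",
                  se_out = "standard_error", p_out = "p_value",
                  eaf_out = "effect_allele_frequency"),
    by = "variant_id")
  if (nrow(j) == 0) {
    rlang::abort(paste0("no shared variants between exposure '", exp_id,
                        "' and outcome '", out_id, "'"),
                 class = "mrtriad_empty_harmonization_error")
  }
  drops <- tibble::tibble(variant_id = character(0), reason = character(0))
  add_drop <- function(ids, reason) {
    if (length(ids) > 0) {
      drops <<- dplyr::bind_rows(drops,
                                 tibble::tibble(variant_id = ids,
                                                reason = reason))
    }
  }

  same <- j$effect_allele == j$ea_out & j$other_allele == j$oa_out
  swapped <- j$effect_allele == j$oa_out & j$other_allele == j$ea_out
  add_drop(j$variant_id[!(same | swapped)], "allele_mismatch")
  j <- j[same | swapped, , drop = FALSE]
  flip <- j$effect_allele == j$oa_out & j$other_allele == j$ea_out
  j$beta_out[flip] <- -j$beta_out[flip]
  j$eaf_out[flip] <- 1 - j$eaf_out[flip]
  j$sign_flipped <- flip

  pal <- is_palindromic(j$effect_allele, j$other_allele)
  if (palindrome_rescue) {
    resolvable <- pal & !is.na(j$eaf_exp) & !is.na(j$eaf_out) &
      abs(j$eaf_exp - 0.5) > eaf_tolerance & abs(j$eaf_out - 0.5) > eaf_tolerance
    discordant <- resolvable & (j$eaf_exp - 0.5) * (j$eaf_out - 0.5) < 0
    j$beta_out[discordant] <- -j$beta_out[discordant]
    j$eaf_out[discordant] <- 1 - j$eaf_out[discordant]
    j$sign_flipped[discordant] <- !j$sign_flipped[discordant]
    drop_pal <- pal & !resolvable
  } else {
    drop_pal <- pal
  }
  add_drop(j$variant_id[drop_pal], "palindromic")
  j <- j[!drop_pal, , drop = FALSE]

  if (!is.null(outcome_p_threshold)) {
    out_assoc <- j$p_out < outcome_p_threshold
    add_drop(j$variant_id[out_assoc], "outcome_associated")
    j <- j[!out_assoc, , drop = FALSE]
  }
  j <- dplyr::select(j, -"ea_out", -"oa_out")
  attr(j, "exposure_id") <- exp_id
  attr(j, "outcome_id") <- out_id
  attr(j, "drops") <- drops
  class(j) <- c("mr_harmonized", class(j))
  j
}
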