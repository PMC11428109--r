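# Study orchestration: forward MR screen, reverse-MR filter, mediation
# screen, and a reproducible report bundle.

#' Forward MR screen of many exposures against one outcome
#'
#' For each exposure: select instruments, harmonize against the outcome,
#' run the estimator panel and (when at least four instruments remain) the
#' sensitivity battery. An exposure is `retained` when its random-effects
#' IVW p-value is below `alpha`; exposures ending with fewer than two
#' usable instruments get disposition `dropped_insufficient_instruments`.
#' Per-exposure failures never abort the batch.
#'
#' @param exposures Named list of `sumstats` tibbles.
#' @param outcome Outcome `sumstats`.
#' @param config [selection_config()] for the exposure legs.
#' @param alpha Significance gate applied to the IVW p-value.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param n_sim MR-PRESSO replicates.
#' @param seed RNG seed for the stochastic methods.
#' @param sensitivity Run the sensitivity battery (default `TRUE`).
#' @return Tibble with one row per exposure: `exposure`, `disposition`,
#'   `n_snp`, `beta`, `se`, `p_value`, `or`, `ci_low`, `ci_high`,
#'   `p_fdr` (Benjamini-Hochberg over the screened IVW p-values, reported
#'   for transparency, never gated on), and list-columns `mr` (all methods)
#'   and `sens` (sensitivity reports).
#' @export
forward_screen <- function(exposures, outcome, config = selection_config(),
                           alpha = 0.05, n_boot = 1000, n_sim = 1000,
                           seed = NULL, sensitivity = TRUE) {
  stopifnot(is.list(exposures), length(exposures) > 0)
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, trait_id, "")
  }
  rows <- purrr::imap(exposures, function(stats, nm) {
    res <- tibble::tibble(
      exposure = nm, disposition = "dropped_insufficient_instruments",
      n_snp = 0L, beta = NA_real_, se = NA_real_, p_value = NA_real_,
      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      mr = list(NULL), sens = list(NULL))
    inst <- select_instruments(stats, config)
    if (nrow(inst) == 0) return(res)
    h <- tryCatch(
      harmonize(inst, outcome,
                outcome_p_threshold = config$outcome_p_threshold),
      mrtriad_empty_harmonization_error = function(e) NULL)
    if (is.null(h) || nrow(h) < 2) return(res)
    mr <- mr_all(h, n_boot = n_boot, seed = seed)
    ivw <- mr[mr$method == "ivw_re", ]
    sens <- if (sensitivity && nrow(h) >= 4) {
      sensitivity_report(h, n_sim = n_sim, seed = seed)
    } else NULL
    tibble::tibble(
      exposure = nm,
      disposition = if (ivw$p_value < alpha) "retained" else
        "dropped_not_significant",
      n_snp = nrow(h), beta = ivw$beta, se = ivw$se, p_value = ivw$p_value,
      or = ivw$or, ci_low = ivw$ci_low, ci_high = ivw$ci_high,
      mr = list(mr), sens = list(sens))
  })
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- stats::p.adjust(out$p_value, method = "BH")
  dplyr::relocate(out, "p_fdr", .after = "p_value")
}

#' Reverse-MR filter of a forward screen
#'
#' Re-runs MR with the roles swapped — the outcome as exposure, at
#' genome-wide significance by default — against each screened exposure.
#' Exposures showing a significant reverse effect (IVW `p < alpha`) are
#' re-dispositioned `dropped_reverse_significant`; the rest keep their
#' forward disposition. If the outcome has no instruments at the reverse
#' threshold, all dispositions are unchanged (with a warning).
#'
#' @param screen Result of [forward_screen()].
#' @param outcome Outcome `sumstats` (now acting as exposure).
#' @param exposures The named list screened forward (now acting as
#'   outcomes).
#' @param reverse_config [selection_config()] for the reverse leg
#'   (default `p_threshold = 5e-8`).
#' @param alpha Significance gate on the reverse IVW p-value.
#' @return `screen` with added columns `reverse_p_value`, `reverse_n_snp`,
#'   and updated `disposition`.
#' @export
reverse_filter <- function(screen, outcome, exposures,
                           reverse_config = selection_config(p_threshold = 5e-8),
                           alpha = 0.05) {
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, trait_id, "")
  }
  if (trait_id(outcome) %in% names(exposures)) {
    rlang::abort("outcome appears among the exposures: self-pair rejected",
                 class = "mrtriad_config_error")
  }
  inst <- select_instruments(outcome, reverse_config)
  screen$reverse_p_value <- NA_real_
  screen$reverse_n_snp <- 0L
  if (nrow(inst) < 2) {
    rlang::warn("outcome has no instruments at the reverse threshold; dispositions unchanged")
    return(screen)
  }
  for (i in seq_len(nrow(screen))) {
    nm <- screen$exposure[i]
    h <- tryCatch(
      harmonize(inst, exposures[[nm]],
                outcome_p_threshold = reverse_config$outcome_p_threshold),
      mrtriad_empty_harmonization_error = function(e) NULL)
    if (is.null(h) || nrow(h) < 2) next
    fit <- mr_ivw(h, "random")
    screen$reverse_p_value[i] <- fit$p_value
    screen$reverse_n_snp[i] <- nrow(h)
    if (fit$p_value < alpha && screen$disposition[i] == "retained") {
      screen$disposition[i] <- "dropped_reverse_significant"
    }
  }
  screen
}

#' Study run configuration
#'
#' Either file paths (`exposure_paths`, `mediator_paths`, `outcome_path`)
#' or a synthetic-study block (`synthetic`, a list of arguments for
#' [simulate_study()]) must be supplied for the trait sets — not both.
#'
#' @param exposure_paths,mediator_paths,outcome_path TSV paths, or `NULL`
#'   when running synthetically.
#' @param synthetic `NULL`, or a list of arguments passed to
#'   [simulate_study()].
#' @param forward_config,reverse_config [selection_config()]s for the two
#'   directions. The forward default disables the outcome-association
#'   exclusion, which in simulated studies with a real causal signal would
#'   remove the very instruments carrying it; pass a threshold to enable it.
#'   The reverse default keeps the exclusion (at `1e-5`), where it guards
#'   against instruments shared with the original exposure masquerading as
#'   reverse causation.
#' @param alpha Significance level for all gates.
#' @param out_dir Output directory for the report bundle.
#' @param seed RNG seed governing every stochastic step.
#' @param n_boot,n_sim Bootstrap / MR-PRESSO replicates.
#' @param plots Write forest/bar plot files.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(exposure_paths = NULL, mediator_paths = NULL,
                       outcome_path = NULL, synthetic = NULL,
                       forward_config = selection_config(outcome_p_threshold = NULL),
                       reverse_config = selection_config(p_threshold = 5e-8),
                       alpha = 0.05, out_dir = "mrtriad_run", seed = 1L,
                       n_boot = 1000, n_sim = 1000, plots = TRUE) {
  has_files <- !is.null(outcome_path)
  has_synth <- !is.null(synthetic)
  if (has_files == has_synth) {
    rlang::abort("supply exactly one of file inputs or a synthetic block",
                 class = "mrtriad_config_error")
  }
  structure(list(exposure_paths = exposure_paths,
                 mediator_paths = mediator_paths,
                 outcome_path = outcome_path, synthetic = synthetic,
                 forward_config = forward_config,
                 reverse_config = reverse_config, alpha = alpha,
                 out_dir = out_dir, seed = seed, n_boot = n_boot,
                 n_sim = n_sim, plots = plots),
            class = "run_config")
}

write_result_tsv <- function(x, dir, name) {
  # drop list-columns; serialize the rest deterministically
  x <- tibble::as_tibble(x)
  x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(x, file.path(dir, name), na = "NA", progress = FALSE)
}

#' Run the full study workflow
#'
#' Executes the forward screen, the reverse-MR filter, the mediator screen
#' (mediators against the outcome), and the two-step mediation screen, and
#' writes every intermediate table (TSV), a run-metadata file (YAML: seed,
#' thresholds, package version) and, optionally, forest/bar plots to
#' `config$out_dir`. Completion, not significance, determines success; a
#' stage with empty input is recorded in the metadata and downstream stages
#' are skipped.
#'
#' @param config A [run_config()].
#' @return A list with `screen` (forward+reverse ScreenResult table),
#'   `mediator_screen`, `mediation` (mediation table), `out_dir`, invisibly
#'   also written to disk.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    if (is.null(args$config)) args$config <- sim_config(seed = config$seed)
    study <- do.call(simulate_study, args)
    exposures <- study$exposures
    mediators <- study$mediators
    outcome <- study$outcome
  } else {
    exposures <- purrr::map(config$exposure_paths, read_sumstats, quiet = TRUE)
    names(exposures) <- vapply(exposures, trait_id, "")
    mediators <- if (is.null(config$mediator_paths)) list() else {
      m <- purrr::map(config$mediator_paths, read_sumstats, quiet = TRUE)
      names(m) <- vapply(m, trait_id, "")
      m
    }
    outcome <- read_sumstats(config$outcome_path, quiet = TRUE)
  }

  notes <- character(0)
  screen <- forward_screen(exposures, outcome,
                           config = config$forward_config,
                           alpha = config$alpha, n_boot = config$n_boot,
                           n_sim = config$n_sim, seed = config$seed)
  screen <- reverse_filter(screen, outcome, exposures,
                           reverse_config = config$reverse_config,
                           alpha = config$alpha)
  write_result_tsv(screen, config$out_dir, "screen.tsv")

  mr_table <- dplyr::bind_rows(purrr::compact(screen$mr))
  if (nrow(mr_table) > 0) {
    write_result_tsv(mr_table, config$out_dir, "mr_results.tsv")
  }
  sens_list <- purrr::compact(screen$sens)
  if (length(sens_list) > 0) {
    sens_tbl <- dplyr::bind_rows(purrr::map(sens_list, glance))
    sens_tbl <- dplyr::bind_cols(
      tibble::tibble(exposure = screen$exposure[!purrr::map_lgl(screen$sens, is.null)]),
      sens_tbl)
    write_result_tsv(sens_tbl, config$out_dir, "sensitivity.tsv")
    loo_tbl <- dplyr::bind_rows(purrr::imap(
      stats::setNames(purrr::map(sens_list, "loo"),
                      screen$exposure[!purrr::map_lgl(screen$sens, is.null)]),
      ~ dplyr::mutate(.x, exposure = .y, .before = 1)))
    write_result_tsv(loo_tbl, config$out_dir, "leave_one_out.tsv")
  }

  retained <- screen$exposure[screen$disposition == "retained"]
  mediator_screen_tbl <- NULL
  mediation_tbl <- NULL
  if (length(mediators) == 0) {
    notes <- c(notes, "no mediators supplied: mediation stages skipped")
  } else if (length(retained) == 0) {
    notes <- c(notes, "no exposures retained: mediation stages skipped")
  } else {
    mediator_screen_tbl <- forward_screen(
      mediators, outcome, config = config$forward_config,
      alpha = config$alpha, n_boot = config$n_boot, n_sim = config$n_sim,
      seed = config$seed, sensitivity = FALSE)
    write_result_tsv(mediator_screen_tbl, config$out_dir,
                     "mediator_screen.tsv")
    sig_med <- mediator_screen_tbl$exposure[
      mediator_screen_tbl$disposition == "retained"]
    if (length(sig_med) == 0) {
      notes <- c(notes, "no mediators significant on the outcome: mediation table empty")
      mediation_tbl <- tibble::tibble()
    } else {
      mediation_tbl <- mediation_screen(
        exposures[retained], mediators[sig_med], outcome,
        config = config$forward_config, alpha = config$alpha)
    }
    write_result_tsv(mediation_tbl, config$out_dir, "mediation.tsv")
  }

  meta <- list(
    package = "mrtriad",
    version = as.character(utils::packageVersion("mrtriad")),
    seed = config$seed,
    alpha = config$alpha,
    forward_p_threshold = config$forward_config$p_threshold,
    reverse_p_threshold = config$reverse_config$p_threshold,
    r2_threshold = config$forward_config$r2_threshold,
    clump_window_kb = config$forward_config$clump_window_kb,
    f_min = config$forward_config$f_min,
    n_boot = config$n_boot,
    n_sim = config$n_sim,
    synthetic = !is.null(config$synthetic),
    notes = as.list(notes))
  yaml::write_yaml(meta, file.path(config$out_dir, "run_metadata.yaml"))

  if (isTRUE(config$plots)) {
    mr_plot_tbl <- screen[!is.na(screen$beta), ]
    if (nrow(mr_plot_tbl) > 0) {
      p <- plot_forest(dplyr::mutate(mr_plot_tbl, method = "ivw_re"))
      ggplot2::ggsave(file.path(config$out_dir, "forest.png"), p,
                      width = 7, height = 1 + 0.4 * nrow(mr_plot_tbl),
                      dpi = 150)
    }
    if (!is.null(mediation_tbl) && nrow(mediation_tbl) > 0) {
      p <- plot_mediation(mediation_tbl)
      ggplot2::ggsave(file.path(config$out_dir, "mediation.png"), p,
                      width = 7, height = 4, dpi = 150)
    }
  }
  invisible(list(screen = screen, mediator_screen = mediator_screen_tbl,
                 mediation = mediation_tbl, out_dir = config$out_dir))
}
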