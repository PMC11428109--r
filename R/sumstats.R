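# GWAS summary-statistics tables: construction, validation, TSV IO.

#' Canonical summary-statistics column names
#'
#' The column dialect used throughout the package, modelled on the
#' GWAS-SSF family of headers used by GWAS Catalog submissions.
#'
#' @return Character vector of the ten canonical column names.
#' @export
sumstats_columns <- function() {
  c("variant_id", "chromosome", "base_pair_location",
    "effect_allele", "other_allele", "effect_allele_frequency",
    "beta", "standard_error", "p_value", "n")
}

#' Build a validated summary-statistics tibble
#'
#' Validates and normalises one trait's per-variant association table.
#' Alleles are upper-cased; rows violating the row-level invariants
#' (`standard_error > 0`, `p_value` in (0, 1], non-empty distinct alleles)
#' are dropped with a message reporting the count. Duplicate `variant_id`s
#' are resolved by keeping the record with the smallest p-value
#' (ties broken by row order); the rest are dropped with a message.
#'
#' @param x A data frame with (at least) the columns of
#'   [sumstats_columns()]. `effect_allele_frequency` may be missing or `NA`.
#' @param trait_id Short identifier for the trait (stored as an attribute).
#' @param trait_name Human-readable trait name.
#' @param quiet Suppress drop messages.
#' @return A tibble with the canonical columns, attributes `trait_id` and
#'   `trait_name`, and class `"sumstats"`.
#' @export
sumstats <- function(x, trait_id = "trait", trait_name = trait_id,
                     quiet = FALSE) {
  x <- tibble::as_tibble(x)
  required <- setdiff(sumstats_columns(), "effect_allele_frequency")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("summary-statistics table is missing mandatory column(s): ",
             paste(missing_cols, collapse = ", "),
             "; available: ", paste(names(x), collapse = ", ")),
      class = "mrtriad_format_error")
  }
  if (!"effect_allele_frequency" %in% names(x)) {
    x$effect_allele_frequency <- NA_real_
  }
  x <- dplyr::select(x, dplyr::all_of(sumstats_columns()))
  x$variant_id <- as.character(x$variant_id)
  x$chromosome <- as.character(x$chromosome)
  # double, not integer: synthetic chromosomes can exceed 2^31 bp
  x$base_pair_location <- as.numeric(x$base_pair_location)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))

  ok <- !is.na(x$beta) & !is.na(x$standard_error) & x$standard_error > 0 &
    !is.na(x$p_value) & x$p_value > 0 & x$p_value <= 1 &
    nzchar(x$effect_allele) & nzchar(x$other_allele) &
    x$effect_allele != x$other_allele & !is.na(x$variant_id)
  n_bad <- sum(!ok)
  if (n_bad > 0 && !quiet) {
    message("sumstats [", trait_id, "]: dropped ", n_bad,
            " row(s) failing validation")
  }
  x <- x[ok, , drop = FALSE]

  if (anyDuplicated(x$variant_id)) {
    n0 <- nrow(x)
    x <- x |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::arrange(.data$p_value, .data$.row) |>
      dplyr::distinct(.data$variant_id, .keep_all = TRUE) |>
      dplyr::arrange(.data$.row) |>
      dplyr::select(-".row")
    if (!quiet) {
      message("sumstats [", trait_id, "]: dropped ", n0 - nrow(x),
              " duplicate variant_id record(s), keeping smallest p-value")
    }
  }
  if (nrow(x) == 0) {
    rlang::abort(paste0("no valid records remain for trait '", trait_id, "'"),
                 class = "mrtriad_empty_input_error")
  }
  attr(x, "trait_id") <- trait_id
  attr(x, "trait_name") <- trait_name
  class(x) <- c("sumstats", class(x))
  x
}

#' Trait identifier of a summary-statistics table
#' @param x A `sumstats` tibble.
#' @return The `trait_id` attribute, or `"trait"` if unset.
#' @export
trait_id <- function(x) {
  id <- attr(x, "trait_id", exact = TRUE)
  if (is.null(id)) "trait" else id
}

#' Read a GWAS summary-statistics table from TSV
#'
#' Reads a tab-separated table (gzip-compressed input is handled
#' transparently by file extension), maps its headers onto the canonical
#' dialect, and validates it via [sumstats()].
#'
#' @param path Path to a TSV (optionally `.gz`) file.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's headers, e.g. `c(variant_id = "SNP", beta = "b")`. Only
#'   the names that differ from the canonical dialect need to be given.
#' @inheritParams sumstats
#' @return A validated `sumstats` tibble.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = NULL,
                          trait_name = NULL, quiet = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "mrtriad_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE, show_col_types = FALSE)
  if (!is.null(column_map)) {
    bad <- setdiff(unname(column_map), names(raw))
    if (length(bad) > 0) {
      rlang::abort(
        paste0("column_map refers to absent header(s): ",
               paste(bad, collapse = ", "),
               "; available: ", paste(names(raw), collapse = ", ")),
        class = "mrtriad_format_error")
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  required <- setdiff(c("variant_id", "effect_allele", "other_allele",
                        "beta", "standard_error", "p_value"), names(raw))
  if (length(required) > 0) {
    rlang::abort(
      paste0("cannot resolve mandatory column(s): ",
             paste(required, collapse = ", "),
             "; available headers: ", paste(names(raw), collapse = ", ")),
      class = "mrtriad_format_error")
  }
  if (!"chromosome" %in% names(raw)) raw$chromosome <- "NA"
  if (!"base_pair_location" %in% names(raw)) raw$base_pair_location <- NA_integer_
  if (!"n" %in% names(raw)) raw$n <- NA_real_
  if (nrow(raw) == 0) {
    rlang::abort(paste0("empty summary-statistics table: ", path),
                 class = "mrtriad_empty_input_error")
  }
  if (is.null(trait_id)) {
    trait_id <- sub("\\.tsv(\\.gz)?$", "", basename(path))
  }
  if (is.null(trait_name)) trait_name <- trait_id
  sumstats(raw, trait_id = trait_id, trait_name = trait_name, quiet = quiet)
}

#' Write a summary-statistics table to TSV
#'
#' Columns are written in the canonical order of [sumstats_columns()];
#' missing effect-allele frequencies are serialized as `NA`.
#'
#' @param x A `sumstats` tibble (or a data frame with the canonical columns).
#' @param path Output path; a `.gz` suffix writes gzip-compressed output.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- tibble::as_tibble(x)[, sumstats_columns()]
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
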