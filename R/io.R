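#' Read a study-level effect size table from CSV
#'
#' Reads a CSV of study-level standardized mean differences with required
#' columns `phenomenon_id`, `study_label`, `estimate`, and exactly one of
#' `variance` or `standard_error` (when both are present they must agree:
#' `variance == standard_error^2` within 1e-6). An optional logical
#' `direction_flip` column negates flagged estimates on input, so that
#' every phenomenon ends up sign-harmonized with the hypothesized direction
#' positive. Column names in external datasets can be adapted via
#' `mapping` — a named character vector (`c(theirs = "ours")`) or the path
#' to a two-column `from,to` CSV; a template mapping for external
#' repository layouts ships in
#' `system.file("extdata", "column_mapping_template.csv", package = "replimeta")`.
#'
#' @param path CSV file path.
#' @param mapping Optional column-name mapping (named character vector or
#'   CSV path with columns `from`, `to`).
#' @param quiet Suppress the per-phenomenon study-count message.
#' @return A validated study tibble (columns `phenomenon_id`,
#'   `study_label`, `estimate`, `variance`).
#' @export
read_study_table <- function(path, mapping = NULL, quiet = FALSE) {
  if (!file.exists(path)) {
    stop("Study table not found: ", path, call. = FALSE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tab <- apply_mapping(tab, mapping)

  for (col in c("phenomenon_id", "study_label", "estimate")) {
    if (!col %in% names(tab)) {
      stop("Study table is missing required column `", col, "`.",
           call. = FALSE)
    }
  }
  has_var <- "variance" %in% names(tab)
  has_se <- "standard_error" %in% names(tab)
  if (!has_var && !has_se) {
    stop("Study table must contain `variance` or `standard_error`.",
         call. = FALSE)
  }
  if (has_var && has_se) {
    off <- abs(tab$variance - tab$standard_error^2)
    if (any(!is.finite(off)) || any(off > 1e-6)) {
      bad <- tab$study_label[which(!is.finite(off) | off > 1e-6)]
      stop("`variance` and `standard_error^2` disagree beyond 1e-6 for: ",
           paste(bad, collapse = ", "), ".", call. = FALSE)
    }
  }
  if (!has_var) tab$variance <- tab$standard_error^2

  if ("direction_flip" %in% names(tab)) {
    flip <- as.logical(tab$direction_flip)
    flip[is.na(flip)] <- FALSE
    tab$estimate <- ifelse(flip, -tab$estimate, tab$estimate)
    tab$direction_flip <- NULL
  }
  tab$standard_error <- NULL
  tab <- validate_studies(tab)
  tab <- dplyr::relocate(tab, "phenomenon_id", "study_label",
                         "estimate", "variance")
  if (!quiet) {
    counts <- table(tab$phenomenon_id)
    message("Read ", nrow(tab), " studies across ", length(counts),
            " phenomena (",
            paste(names(counts), counts, sep = ": ", collapse = ", "), ")")
  }
  tab
}

apply_mapping <- function(tab, mapping) {
  if (is.null(mapping)) return(tab)
  if (is.character(mapping) && length(mapping) == 1L && is.null(names(mapping))) {
    map_tab <- readr::read_csv(mapping, show_col_types = FALSE,
                               progress = FALSE)
    if (!all(c("from", "to") %in% names(map_tab))) {
      stop("A mapping CSV must have columns `from` and `to`.", call. = FALSE)
    }
    mapping <- stats::setNames(map_tab$to, map_tab$from)
  }
  hit <- names(mapping) %in% names(tab)
  names(tab)[match(names(mapping)[hit], names(tab))] <- unname(mapping[hit])
  tab
}

#' Write a study table to CSV
#'
#' @param studies A study tibble (see [read_study_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(studies, path) {
  studies <- validate_studies(studies)
  keep <- intersect(c("phenomenon_id", "study_label", "estimate", "variance"),
                    names(studies))
  readr::write_csv(studies[, keep, drop = FALSE], path)
  invisible(path)
}

#' Read a table of MLR summary estimates
#'
#' Requires columns `phenomenon_id`, `mlr_estimate`, and one of
#' `mlr_variance` or `mlr_se`.
#'
#' @param path CSV file path.
#' @return A tibble with columns `phenomenon_id`, `mlr_estimate`,
#'   `mlr_variance`.
#' @export
read_mlr_table <- function(path) {
  if (!file.exists(path)) stop("MLR table not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("phenomenon_id", "mlr_estimate")) {
    if (!col %in% names(tab)) {
      stop("MLR table is missing required column `", col, "`.",
           call. = FALSE)
    }
  }
  if (!"mlr_variance" %in% names(tab)) {
    if (!"mlr_se" %in% names(tab)) {
      stop("MLR table must contain `mlr_variance` or `mlr_se`.",
           call. = FALSE)
    }
    tab$mlr_variance <- tab$mlr_se^2
    tab$mlr_se <- NULL
  }
  if (any(!is.finite(tab$mlr_variance)) || any(tab$mlr_variance <= 0)) {
    stop("All `mlr_variance` values must be finite and > 0.", call. = FALSE)
  }
  if (anyDuplicated(tab$phenomenon_id)) {
    stop("Duplicate `phenomenon_id` in MLR table.", call. = FALSE)
  }
  tab[, c("phenomenon_id", "mlr_estimate", "mlr_variance")]
}

#' Write / read a synthetic phenomenon suite as CSV files
#'
#' `write_suite()` writes `studies.csv`, `mlr.csv` and `truth.csv` into a
#' directory using the same schema [read_study_table()] and
#' [read_mlr_table()] read; `read_suite()` reads them back (the truth
#' table is optional, as real data has none).
#'
#' @param suite A `phenomenon_suite` from [simulate_phenomenon_suite()].
#' @param dir Directory (created if needed).
#' @return `write_suite()`: `dir`, invisibly. `read_suite()`: a
#'   `phenomenon_suite` list.
#' @export
write_suite <- function(suite, dir) {
  stopifnot(inherits(suite, "phenomenon_suite"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_study_table(suite$studies, file.path(dir, "studies.csv"))
  readr::write_csv(suite$mlr, file.path(dir, "mlr.csv"))
  if (!is.null(suite$truth)) {
    readr::write_csv(suite$truth, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' @rdname write_suite
#' @export
read_suite <- function(dir) {
  studies <- read_study_table(file.path(dir, "studies.csv"), quiet = TRUE)
  mlr <- read_mlr_table(file.path(dir, "mlr.csv"))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  structure(list(studies = studies, mlr = mlr, truth = truth),
            class = "phenomenon_suite")
}

#' Read a pipeline configuration file
#'
#' A flat YAML file supplying any of `tau2_method`, `interval_method`,
#' `alpha`, `n_boot`, `seed`, `eta_list`; missing keys fall back to the
#' package defaults (PM, wald_z, 0.05, 1000, no default seed, empty eta
#' list). `seed` has no default: reproducibility requires it explicitly.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return A named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(tau2_method = "PM", interval_method = "wald_z",
                   alpha = 0.05, n_boot = 1000L, seed = NULL,
                   eta_list = numeric(0))
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("Config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("Unknown config key(s): ", paste(unknown, collapse = ", "), ".",
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, cfg)
  out$eta_list <- as.numeric(out$eta_list)
  out
}

#' Write a comparison report to CSV and JSON
#'
#' Writes `per_phenomenon.csv`, `summary.csv`, `correlation.csv` (when
#' computed), `corrected.csv` (when eta corrections were requested) and a
#' single `report.json` mirroring all of them plus the configuration.
#'
#' @param report An `mlr_comparison` from [run_full_comparison()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mlr_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$per_phenomenon,
                   file.path(dir, "per_phenomenon.csv"))
  readr::write_csv(report$summary, file.path(dir, "summary.csv"))
  if (!is.null(report$correlation)) {
    readr::write_csv(report$correlation, file.path(dir, "correlation.csv"))
  }
  if (nrow(report$corrected)) {
    readr::write_csv(report$corrected, file.path(dir, "corrected.csv"))
  }
  jsonlite::write_json(
    list(per_phenomenon = report$per_phenomenon,
         correlation = report$correlation,
         summary = report$summary,
         corrected = report$corrected,
         config = report$config),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(dir)
}
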