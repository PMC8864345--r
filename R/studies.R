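#' Validate a study-level effect size table
#'
#' Checks that a data frame of study-level effect estimates satisfies the
#' contracts assumed throughout the package: an `estimate` column of finite
#' standardized mean differences (Cohen's d scale), a strictly positive
#' `variance` column (sampling variance of the estimate), and, when present,
#' unique `study_label`s within each phenomenon. A missing `study_label`
#' column is filled in with `"study_1"`, `"study_2"`, ... so downstream
#' results can always be traced back to a study.
#'
#' All estimates are assumed to be sign-harmonized so that the hypothesized
#' direction of the effect is positive; [read_study_table()] can negate
#' flagged rows on input via its `direction_flip` column.
#'
#' @param data A data frame with at least columns `estimate` and `variance`.
#' @param require_k Minimum number of studies required (default 1).
#' @return The validated data as a tibble, with a `study_label` column.
#' @export
#' @examples
#' validate_studies(data.frame(estimate = c(0.2, 0.5), variance = c(0.04, 0.02)))
validate_studies <- function(data, require_k = 1L) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame of study-level estimates.", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  for (col in c("estimate", "variance")) {
    if (!col %in% names(data)) {
      stop("`data` is missing required column `", col, "`.", call. = FALSE)
    }
  }
  if (nrow(data) < require_k) {
    stop("`data` must contain at least ", require_k, " stud",
         if (require_k == 1L) "y" else "ies",
         " (got ", nrow(data), ").", call. = FALSE)
  }
  if (nrow(data) > 0 && !all(is.finite(data$estimate))) {
    stop("All `estimate` values must be finite.", call. = FALSE)
  }
  if (nrow(data) > 0 && (!all(is.finite(data$variance)) || any(data$variance <= 0))) {
    bad <- which(!is.finite(data$variance) | data$variance <= 0)
    lab <- if ("study_label" %in% names(data)) {
      paste(data$study_label[bad], collapse = ", ")
    } else {
      paste("row", paste(bad, collapse = ", "))
    }
    stop("All `variance` values must be finite and > 0 (offending: ", lab, ").",
         call. = FALSE)
  }
  if (!"study_label" %in% names(data)) {
    data$study_label <- paste0("study_", seq_len(nrow(data)))
  }
  dup_by <- if ("phenomenon_id" %in% names(data)) {
    paste(data$phenomenon_id, data$study_label)
  } else {
    data$study_label
  }
  if (anyDuplicated(dup_by)) {
    stop("`study_label` values must be unique within a phenomenon.", call. = FALSE)
  }
  data
}

# Split a possibly multi-phenomenon study table into a named list of
# per-phenomenon tibbles, preserving first-appearance order.
split_phenomena <- function(data) {
  if (!"phenomenon_id" %in% names(data)) {
    return(list(phenomenon_1 = data))
  }
  ids <- unique(data$phenomenon_id)
  out <- lapply(ids, function(id) data[data$phenomenon_id == id, , drop = FALSE])
  names(out) <- as.character(ids)
  out
}
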