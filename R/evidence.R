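#' The evidence-base table
#'
#' An evidence base is a tidy tibble with one row per primary study
#' extracted from a systematic review, holding either raw binary outcome
#' data or a reported proportion with its 95% confidence interval:
#'
#' * `review_id`, `study_id` — opaque labels; `study_id` unique within a
#'   review.
#' * `design` — `"SAT"` (prospective interventional single-arm trial) or
#'   `"SAC"` (observational single-arm cohort). Parsed case-insensitively;
#'   anything else is rejected rather than guessed, because design
#'   misclassification is a real failure mode in source reviews.
#' * `events`, `n` — counts mode: number of events and sample size.
#' * `estimate`, `ci_low`, `ci_high` — CI mode: a proportion in `[0, 1]`
#'   with its reported 95% bounds (some reviews publish only these).
#' * `clin_het_flag` — logical; marked clinically heterogeneous by
#'   reviewer consensus, removed in the sensitivity analysis.
#' * `outcome` — outcome label the row contributes to.
#'
#' Exactly one of the two modes must be populated per row.
#'
#' @param data A data frame with the columns above.
#' @return `validate_evidence()` returns `data` as a tibble with
#'   normalised types (invisibly usable in a pipe); it aborts with a
#'   message naming the offending rows when any invariant is violated.
#' @examples
#' ev <- tibble::tibble(
#'   review_id = "R01", study_id = c("s1", "s2"), design = c("SAT", "SAC"),
#'   events = c(5L, NA), n = c(10L, NA),
#'   estimate = c(NA, 0.5), ci_low = c(NA, 0.4), ci_high = c(NA, 0.6),
#'   clin_het_flag = FALSE, outcome = "response"
#' )
#' validate_evidence(ev)
#' @export
validate_evidence <- function(data) {
  required <- c(
    "review_id", "study_id", "design", "events", "n",
    "estimate", "ci_low", "ci_high", "clin_het_flag", "outcome"
  )
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("evidence base is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "satmeta_format_error"
    )
  }
  if (nrow(data) == 0) {
    abort("evidence base contains no study records",
          class = "satmeta_format_error")
  }

  out <- as_tibble(data) %>%
    mutate(
      review_id = as.character(.data$review_id),
      study_id = as.character(.data$study_id),
      design = toupper(trimws(as.character(.data$design))),
      events = as.integer(.data$events),
      n = as.integer(.data$n),
      dplyr::across(c("estimate", "ci_low", "ci_high"), as.numeric),
      clin_het_flag = as.logical(.data$clin_het_flag),
      outcome = as.character(.data$outcome)
    )

  problems <- character()
  bad_rows <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0) {
      problems <<- c(problems, paste0(
        "row(s) ", paste(head(idx, 5), collapse = ", "),
        if (length(idx) > 5) ", ..." else "", ": ", msg
      ))
    }
  }

  counts_mode <- !is.na(out$events) & !is.na(out$n)
  ci_mode <- !is.na(out$estimate) & !is.na(out$ci_low) & !is.na(out$ci_high)
  bad_rows(!out$design %in% the_designs,
           "design must be 'SAT' or 'SAC'")
  bad_rows(counts_mode & ci_mode,
           "both counts (events, n) and CI (estimate, ci_low, ci_high) populated")
  bad_rows(!counts_mode & !ci_mode,
           "neither counts (events, n) nor CI (estimate, ci_low, ci_high) fully populated")
  bad_rows(counts_mode & (out$n < 1L | out$events < 0L | out$events > out$n),
           "counts must satisfy 0 <= events <= n, n >= 1")
  in01 <- function(x) !is.na(x) & x >= 0 & x <= 1
  bad_rows(ci_mode & !(in01(out$estimate) & in01(out$ci_low) & in01(out$ci_high)),
           "estimate and CI bounds must be proportions in [0, 1]")
  bad_rows(ci_mode & (out$ci_low > out$estimate | out$estimate > out$ci_high),
           "CI bounds must satisfy ci_low <= estimate <= ci_high")
  bad_rows(is.na(out$clin_het_flag), "clin_het_flag must be TRUE/FALSE")

  dup <- duplicated(out[, c("review_id", "study_id")])
  bad_rows(dup, "duplicated (review_id, study_id)")

  if (length(problems) > 0) {
    abort(
      c("invalid evidence base:", setNames(problems, rep("x", length(problems)))),
      class = "satmeta_validation_error"
    )
  }
  out
}

#' Read or write an evidence-base CSV
#'
#' The canonical on-disk format is a UTF-8 comma-separated file with one
#' row per primary study and columns `review_id, study_id, design,
#' events, n, estimate, ci_low, ci_high, clin_het_flag, outcome`
#' (proportions as decimals in `[0, 1]`). `read_evidence()` validates on
#' load and reports offending rows; `write_evidence()` emits the same
#' schema, so the two round-trip.
#'
#' @param path Path to a CSV file.
#' @param data A validated evidence-base tibble.
#' @return `read_evidence()` returns a validated evidence tibble;
#'   `write_evidence()` returns `data` invisibly.
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "satmeta_format_error")
  }
  raw <- tryCatch(
    suppressWarnings(readr::read_csv(
      path,
      col_types = readr::cols(
        review_id = readr::col_character(),
        study_id = readr::col_character(),
        design = readr::col_character(),
        events = readr::col_integer(),
        n = readr::col_integer(),
        estimate = readr::col_double(),
        ci_low = readr::col_double(),
        ci_high = readr::col_double(),
        clin_het_flag = readr::col_logical(),
        outcome = readr::col_character()
      ),
      progress = FALSE, show_col_types = FALSE
    )),
    error = function(e) {
      abort(paste0("could not parse evidence CSV: ", conditionMessage(e)),
            class = "satmeta_format_error")
    }
  )
  validate_evidence(raw)
}

#' @rdname read_evidence
#' @export
write_evidence <- function(data, path) {
  out <- validate_evidence(data)
  readr::write_csv(
    out[, c("review_id", "study_id", "design", "events", "n",
            "estimate", "ci_low", "ci_high", "clin_het_flag", "outcome")],
    path, progress = FALSE
  )
  invisible(data)
}

#' Pick the outcome with the most contributing studies
#'
#' When a review reports several interventions or outcomes, the one with
#' the largest number of contributing studies is selected for
#' extraction. Ties are broken by lexicographic order of the outcome
#' label so the choice is deterministic.
#'
#' @param data A data frame with at least an `outcome` column (one row
#'   per contributing study).
#' @return The selected outcome label (length-1 character).
#' @examples
#' df <- tibble::tibble(outcome = c("ORR", "ORR", "PFS"))
#' select_primary_outcome(df) # "ORR"
#' @export
select_primary_outcome <- function(data) {
  if (!is.data.frame(data) || !"outcome" %in% names(data) || nrow(data) == 0) {
    abort("`data` must be a nonempty data frame with an `outcome` column",
          class = "satmeta_domain_error")
  }
  tab <- data %>%
    count(.data$outcome) %>%
    arrange(dplyr::desc(.data$n), .data$outcome)
  tab$outcome[[1]]
}
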