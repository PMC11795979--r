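#' Remove clinically heterogeneous studies
#'
#' Drops every record whose `clin_het_flag` is set. Reviews that lose an
#' entire design subgroup in the process leave the paired comparison set
#' (reason `"subgroup-emptied"`; reviews losing all records are reason
#' `"all-records-flagged"`), but any surviving single-design records are
#' retained so they can still contribute to unpaired heterogeneity
#' summaries.
#'
#' @param data An evidence-base tibble with `clin_het_flag` populated.
#' @return A list with `evidence` (the filtered tibble; zero rows
#'   possible) and `dropped` (tibble `review_id`, `reason` for reviews
#'   that left the paired set).
#' @examples
#' sim <- simulate_evidence(sim_config(outlier_fraction = 0.3, seed = 2))
#' apply_exclusions(sim$evidence)$dropped
#' @export
apply_exclusions <- function(data) {
  data <- validate_evidence(data)
  kept <- filter(data, !.data$clin_het_flag)

  before <- data %>%
    distinct(.data$review_id, .data$design) %>%
    count(.data$review_id, name = "n_designs_before")
  after <- kept %>%
    distinct(.data$review_id, .data$design) %>%
    count(.data$review_id, name = "n_designs_after")

  dropped <- before %>%
    left_join(after, by = "review_id") %>%
    mutate(n_designs_after = tidyr::replace_na(.data$n_designs_after, 0L)) %>%
    filter(.data$n_designs_before == 2L, .data$n_designs_after < 2L) %>%
    mutate(reason = ifelse(.data$n_designs_after == 0L,
                           "all-records-flagged", "subgroup-emptied")) %>%
    select("review_id", "reason")

  if (nrow(kept) == 0) {
    warn("all records are flagged clinically heterogeneous; nothing remains")
  }
  list(evidence = kept, dropped = dropped)
}

#' Sensitivity re-analysis after removing clinically heterogeneous studies
#'
#' Runs the full pipeline (design comparison, cross-review pooling,
#' heterogeneity comparison) on the evidence base as given and again
#' after [apply_exclusions()], and pairs the per-review, per-design
#' I-squared values before and after removal. Groups reduced to a
#' single study have no defined I-squared afterwards and appear with
#' `i2_after = NA`.
#'
#' @param data An evidence-base tibble.
#' @param alpha Significance level for within-review z-tests.
#' @param correction Boundary-count policy, see [study_effects()].
#' @param mode Rank-test mode, see [compare_heterogeneity()].
#' @return An object of class `"satmeta_sensitivity"`: list with `main`
#'   and `reduced` (each a `"satmeta_analysis"`; `reduced` is `NULL`
#'   when nothing survives), `dropped` (from [apply_exclusions()]), and
#'   `i2_deltas` (tibble `review_id`, `design`, `i2_before`,
#'   `i2_after`).
#' @examples
#' sim <- simulate_evidence(sim_config(outlier_fraction = 0.15, seed = 3))
#' sens <- run_sensitivity(sim$evidence)
#' sens$i2_deltas
#' @export
run_sensitivity <- function(data, alpha = 0.05, correction = "add-half",
                            mode = "auto") {
  data <- validate_evidence(data)
  main <- analyze_evidence(data, alpha = alpha, correction = correction,
                           mode = mode)
  excl <- apply_exclusions(data)
  reduced <- if (nrow(excl$evidence) > 0) {
    analyze_evidence(excl$evidence, alpha = alpha, correction = correction,
                     mode = mode)
  }

  long_i2 <- function(cmp, which) {
    cmp %>%
      select("review_id", SAT = "i2_sat", SAC = "i2_sac") %>%
      tidyr::pivot_longer(c("SAT", "SAC"), names_to = "design",
                          values_to = which)
  }
  i2_deltas <- long_i2(main$comparisons, "i2_before") %>%
    left_join(
      if (is.null(reduced)) {
        tibble(review_id = character(), design = character(),
               i2_after = numeric())
      } else {
        long_i2(reduced$comparisons, "i2_after")
      },
      by = c("review_id", "design")
    ) %>%
    filter(!is.na(.data$i2_before) | !is.na(.data$i2_after))

  structure(
    list(main = main, reduced = reduced, dropped = excl$dropped,
         i2_deltas = i2_deltas),
    class = "satmeta_sensitivity"
  )
}

#' @export
print.satmeta_sensitivity <- function(x, ...) {
  cat("== Full data ==\n")
  print(x$main)
  cat(sprintf("\n== Sensitivity (%d review(s) left the paired set%s) ==\n",
              nrow(x$dropped),
              if (nrow(x$dropped) > 0) {
                paste0(": ", paste(x$dropped$review_id, collapse = ", "))
              } else ""))
  if (is.null(x$reduced)) cat("  (no records remain)\n") else print(x$reduced)
  invisible(x)
}
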