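#' Collect per-review I-squared samples by design
#'
#' I-squared is only defined for subgroups with at least two studies, so
#' a review contributes to the paired sample only when both its designs
#' have a defined value, while the unpaired per-design samples take
#' every defined value regardless of pairing.
#'
#' @param comparisons A `"design_comparison"` tibble from
#'   [compare_designs()].
#' @return A list with `paired` (tibble `review_id`, `i2_sat`,
#'   `i2_sac`), and `sat` / `sac` (tibbles `review_id`, `i2`). Empty
#'   tibbles are allowed.
#' @export
collect_i2_samples <- function(comparisons) {
  list(
    paired = comparisons %>%
      filter(!is.na(.data$i2_sat), !is.na(.data$i2_sac)) %>%
      select("review_id", "i2_sat", "i2_sac"),
    sat = comparisons %>%
      filter(!is.na(.data$i2_sat)) %>%
      select("review_id", i2 = "i2_sat"),
    sac = comparisons %>%
      filter(!is.na(.data$i2_sac)) %>%
      select("review_id", i2 = "i2_sac")
  )
}

#' Median and range of an I-squared sample
#'
#' @param i2 Numeric vector of defined I-squared percentages.
#' @return One-row tibble with `n`, `median` (midpoint convention for
#'   even counts), `min`, `max`.
#' @examples
#' summarize_i2(c(10, 20, 30, 40)) # median 25
#' @export
summarize_i2 <- function(i2) {
  if (length(i2) == 0 || anyNA(i2)) {
    abort("`i2` must be a nonempty vector of defined I2 values",
          class = "satmeta_domain_error")
  }
  tibble(n = length(i2), median = median(i2), min = min(i2), max = max(i2))
}

#' Compare heterogeneity between designs across reviews
#'
#' Summarises the per-design I-squared samples (median and range) and
#' tests for a design difference two ways: the Wilcoxon signed-rank
#' test on reviews where both designs have a defined I-squared, and —
#' because paired data are scarce — the Mann-Whitney test on the two
#' unpaired samples.
#'
#' Either test is reported as `NULL` when its input is degenerate
#' (no usable pairs, an empty sample, or all paired differences zero).
#'
#' @param comparisons A `"design_comparison"` tibble.
#' @param mode Test mode passed to [wilcoxon_signed_rank()] and
#'   [mann_whitney_u()].
#' @return An object of class `"het_comparison"`: list with `samples`
#'   (from [collect_i2_samples()]), `summary` (per-design tibble of
#'   `n`, `median`, `min`, `max`), `wilcoxon` and `mann_whitney`
#'   (`"rank_test"` objects or `NULL`).
#' @export
compare_heterogeneity <- function(comparisons, mode = "auto") {
  samples <- collect_i2_samples(comparisons)
  summary <- bind_rows(
    SAT = if (nrow(samples$sat) > 0) summarize_i2(samples$sat$i2),
    SAC = if (nrow(samples$sac) > 0) summarize_i2(samples$sac$i2),
    .id = "design"
  )
  wil <- if (nrow(samples$paired) > 0) {
    tryCatch(
      wilcoxon_signed_rank(samples$paired$i2_sat, samples$paired$i2_sac,
                           mode = mode),
      satmeta_degenerate_error = function(e) NULL
    )
  }
  mw <- if (nrow(samples$sat) > 0 && nrow(samples$sac) > 0) {
    mann_whitney_u(samples$sat$i2, samples$sac$i2, mode = mode)
  }
  structure(
    list(samples = samples, summary = summary,
         wilcoxon = wil, mann_whitney = mw),
    class = "het_comparison"
  )
}

#' @export
print.het_comparison <- function(x, ...) {
  cat("<het_comparison>\n")
  if (nrow(x$summary) > 0) {
    for (i in seq_len(nrow(x$summary))) {
      s <- x$summary[i, ]
      cat(sprintf("  %s: n = %d, median I2 = %.1f%%, range %.1f%%-%.1f%%\n",
                  s$design, s$n, s$median, s$min, s$max))
    }
  }
  if (!is.null(x$wilcoxon)) {
    cat(sprintf("  Wilcoxon signed-rank: W = %g, p = %.5g (%s, %d pairs)\n",
                x$wilcoxon$statistic, x$wilcoxon$p, x$wilcoxon$method,
                x$wilcoxon$n_used))
  }
  if (!is.null(x$mann_whitney)) {
    cat(sprintf("  Mann-Whitney: U = %g, p = %.5g (%s, n = %d/%d)\n",
                x$mann_whitney$statistic, x$mann_whitney$p,
                x$mann_whitney$method,
                x$mann_whitney$n_used[1], x$mann_whitney$n_used[2]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.het_comparison <- function(x, ...) {
  bind_rows(
    if (!is.null(x$wilcoxon)) mutate(tidy(x$wilcoxon), test = "wilcoxon-signed-rank"),
    if (!is.null(x$mann_whitney)) mutate(tidy(x$mann_whitney), test = "mann-whitney")
  )
}
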