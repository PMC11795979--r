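#' Run the full meta-epidemiological pipeline on an evidence base
#'
#' Convenience wrapper chaining the three analysis stages: per-review
#' design comparison ([compare_designs()]), cross-review pooling of the
#' risk differences ([pool_risk_differences()]), and the heterogeneity
#' comparison ([compare_heterogeneity()]).
#'
#' @param data An evidence-base tibble (see [validate_evidence()]).
#' @param alpha Two-sided significance level for within-review z-tests.
#' @param correction Boundary-count policy, see [study_effects()].
#' @param mode Rank-test mode, see [wilcoxon_signed_rank()].
#' @return An object of class `"satmeta_analysis"`: list with
#'   `comparisons` (the `"design_comparison"` tibble), `cross`
#'   (`"cross_review"`, or `NULL` when no review has both designs) and
#'   `heterogeneity` (`"het_comparison"`).
#' @examples
#' sim <- simulate_evidence(sim_config(seed = 11))
#' fit <- analyze_evidence(sim$evidence)
#' glance(fit)
#' @export
analyze_evidence <- function(data, alpha = 0.05, correction = "add-half",
                             mode = "auto") {
  comparisons <- compare_designs(data, alpha = alpha, correction = correction)
  cross <- tryCatch(pool_risk_differences(comparisons),
                    satmeta_domain_error = function(e) NULL)
  het <- compare_heterogeneity(comparisons, mode = mode)
  structure(
    list(comparisons = comparisons, cross = cross, heterogeneity = het),
    class = "satmeta_analysis"
  )
}

#' @export
print.satmeta_analysis <- function(x, ...) {
  cat(sprintf("<satmeta_analysis: %d review(s), %d comparable>\n",
              nrow(x$comparisons), sum(x$comparisons$comparable)))
  if (!is.null(x$cross)) print(x$cross)
  print(x$heterogeneity)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.satmeta_analysis <- function(x, ...) {
  as_tibble(x$comparisons)
}

#' @exportS3Method generics::glance
glance.satmeta_analysis <- function(x, ...) {
  base <- if (is.null(x$cross)) {
    tibble(n_reviews = 0L)
  } else {
    glance(x$cross) %>%
      rename(pooled_rd = "pooled", se_rd = "se", p_rd = "p_z")
  }
  het <- x$heterogeneity
  base %>%
    mutate(
      median_i2_sat = pull_summary(het, "SAT", "median"),
      median_i2_sac = pull_summary(het, "SAC", "median"),
      p_wilcoxon = if (is.null(het$wilcoxon)) NA_real_ else het$wilcoxon$p,
      p_mann_whitney = if (is.null(het$mann_whitney)) NA_real_ else het$mann_whitney$p
    )
}

pull_summary <- function(het, design, col) {
  row <- het$summary[het$summary$design == design, ]
  if (nrow(row) == 0) NA_real_ else row[[col]]
}

#' Write the pipeline's report files
#'
#' Serialises an analysis (or a sensitivity re-analysis) to a directory
#' of CSV files that round-trip through `readr`:
#' `comparisons.csv` (one row per review: subgroup pools, risk
#' difference, CI, direction, significance), `pooled_rd.csv` (the
#' cross-review pooled risk difference with Q, tau2, I2 and rankings),
#' `heterogeneity.csv` (per-design I2 summaries) and `rank_tests.csv`.
#' For a sensitivity object the same set is written under `main/` and
#' `sensitivity/` prefixes, plus `dropped_reviews.csv` and the combined
#' `i2_before_after.csv` backing the before/after heterogeneity plot.
#'
#' @param x A `"satmeta_analysis"` or `"satmeta_sensitivity"` object.
#' @param dir Output directory (created if needed).
#' @return The vector of files written, invisibly.
#' @export
write_reports <- function(x, dir) {
  UseMethod("write_reports")
}

#' @export
write_reports.satmeta_analysis <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    comparisons = file.path(dir, "comparisons.csv"),
    pooled_rd = file.path(dir, "pooled_rd.csv"),
    heterogeneity = file.path(dir, "heterogeneity.csv"),
    rank_tests = file.path(dir, "rank_tests.csv")
  )
  readr::write_csv(as_tibble(x$comparisons), files["comparisons"],
                   progress = FALSE)
  if (!is.null(x$cross)) {
    readr::write_csv(glance(x$cross), files["pooled_rd"], progress = FALSE)
  }
  readr::write_csv(x$heterogeneity$summary, files["heterogeneity"],
                   progress = FALSE)
  tests <- tidy(x$heterogeneity)
  if (nrow(tests) > 0) {
    readr::write_csv(tests, files["rank_tests"], progress = FALSE)
  }
  invisible(files[file.exists(files)])
}

#' @export
write_reports.satmeta_sensitivity <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- write_reports(x$main, file.path(dir, "main"))
  if (!is.null(x$reduced)) {
    written <- c(written,
                 write_reports(x$reduced, file.path(dir, "sensitivity")))
  }
  dropped_path <- file.path(dir, "dropped_reviews.csv")
  readr::write_csv(x$dropped, dropped_path, progress = FALSE)
  deltas_path <- file.path(dir, "i2_before_after.csv")
  readr::write_csv(x$i2_deltas, deltas_path, progress = FALSE)
  invisible(c(written, dropped_path, deltas_path))
}

#' Simulation study of the cross-review estimator
#'
#' Repeatedly simulates an evidence base from `config`, runs the
#' design-comparison pipeline, and summarises how well the pooled risk
#' difference recovers the generating `delta_rd`: mean estimate, bias,
#' RMSE, 95% CI coverage of the truth, and the rejection rate of the
#' two-sided z-test on the pooled difference (the type-I error rate
#' when `delta_rd = 0`).
#'
#' @param config A `"sim_config"`; its `seed` drives the whole study
#'   (replicate `r` uses `seed + r`).
#' @param n_reps Number of replicates (>= 2).
#' @param alpha Significance level for the rejection count.
#' @param correction Boundary-count policy.
#' @return A list of class `"satmeta_recovery"` with `summary` (one-row
#'   tibble: `n_reps`, `delta_rd`, `mean_rd`, `bias`, `rmse`,
#'   `coverage`, `rejection_rate`) and `replicates` (per-replicate
#'   tibble of `pooled_rd`, `se`, `ci_low`, `ci_high`, `p`).
#' @examples
#' run_recovery(sim_config(seed = 1), n_reps = 5)$summary
#' @export
run_recovery <- function(config, n_reps, alpha = 0.05,
                         correction = "add-half") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_reps) || n_reps < 2) {
    abort("`n_reps` must be at least 2", class = "satmeta_config_error")
  }
  base_seed <- config$seed %||% 0
  reps <- purrr::map(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- base_seed + r
    sim <- simulate_evidence(cfg)
    cmp <- suppressMessages(
      compare_designs(sim$evidence, alpha = alpha, correction = correction)
    )
    rd <- pool_risk_differences(cmp)$rd
    tibble(pooled_rd = rd$pooled, se = rd$se,
           ci_low = rd$ci_low, ci_high = rd$ci_high, p = rd$p_z)
  }) %>% bind_rows()

  truth <- config$delta_rd
  summary <- tibble(
    n_reps = as.integer(n_reps),
    delta_rd = truth,
    mean_rd = mean(reps$pooled_rd),
    bias = mean(reps$pooled_rd) - truth,
    rmse = sqrt(mean((reps$pooled_rd - truth)^2)),
    coverage = mean(reps$ci_low <= truth & truth <= reps$ci_high),
    rejection_rate = mean(reps$p < alpha)
  )
  structure(list(summary = summary, replicates = reps),
            class = "satmeta_recovery")
}

#' @export
print.satmeta_recovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<satmeta_recovery: %d replicates, true delta_rd = %g>\n",
           "  mean estimate %.4f (bias %+.4f, rmse %.4f)\n",
           "  95%% CI coverage %.3f, rejection rate %.3f\n"),
    s$n_reps, s$delta_rd, s$mean_rd, s$bias, s$rmse, s$coverage,
    s$rejection_rate
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.satmeta_recovery <- function(x, ...) x$replicates

#' @exportS3Method generics::glance
glance.satmeta_recovery <- function(x, ...) x$summary
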