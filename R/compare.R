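#' Within-review SAT-versus-SAC comparison
#'
#' For every review in the evidence base, the SAT and SAC subgroups are
#' pooled separately with DerSimonian-Laird random-effects
#' meta-analysis, and the between-design risk difference
#' `d = pooled_SAT - pooled_SAC` is formed with its propagated standard
#' error `se_d = sqrt(se_SAT^2 + se_SAC^2)` and Wald 95% interval.
#' A positive `d` means the trials gave the higher estimate.
#'
#' Significance of `d` is judged by a two-sided z-test at `alpha`
#' (equivalently the 95% CI excluding zero when `alpha = 0.05`), and the
#' direction by the sign of `d`; exact zeros are kept in a separate
#' `"tied"` bucket so degenerate synthetic inputs stay deterministic.
#' Reviews lacking one of the two designs are retained in the table with
#' `comparable = FALSE` (their single subgroup is still pooled) but are
#' excluded from everything downstream that needs a difference.
#'
#' @param data An evidence-base tibble (validated on entry).
#' @param alpha Two-sided significance level for the z-test on `d`.
#' @param correction Boundary-count policy passed to [study_effects()].
#' @return A tibble of class `"design_comparison"`, one row per review:
#'   subgroup summaries (`k_*`, `pooled_*`, `se_*`, `i2_*`, `tau2_*`),
#'   the difference `d`, `se_d`, `ci_low`, `ci_high`, `z`, `p`,
#'   `direction` (`"SAT-higher"`, `"SAC-higher"`, `"tied"`),
#'   `significance` (`"sig-SAT-higher"`, `"sig-SAC-higher"`,
#'   `"not-significant"`), and `comparable`.
#' @examples
#' sim <- simulate_evidence(sim_config(seed = 1))
#' compare_designs(sim$evidence)
#' @export
compare_designs <- function(data, alpha = 0.05, correction = "add-half") {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  eff <- study_effects(data, correction = correction)

  nonpool <- eff %>%
    group_by(.data$review_id, .data$design) %>%
    summarise(k = dplyr::n(), n_bad = sum(!.data$poolable), .groups = "drop") %>%
    filter(.data$n_bad > 0, .data$k > 1)
  if (nrow(nonpool) > 0) {
    abort(paste0(
      "zero-variance effects (zero-width CI without correction) cannot be ",
      "pooled with other studies; affected review(s): ",
      paste(unique(nonpool$review_id), collapse = ", ")
    ), class = "satmeta_domain_error")
  }

  by_design <- eff %>%
    group_by(.data$review_id, .data$design) %>%
    summarise(pool = list(dl_stats(.data$y, .data$v)), .groups = "drop") %>%
    mutate(
      k = purrr::map_int(.data$pool, "k"),
      pooled = purrr::map_dbl(.data$pool, "pooled"),
      se = purrr::map_dbl(.data$pool, "se"),
      tau2 = purrr::map_dbl(.data$pool, "tau2"),
      i2 = purrr::map_dbl(.data$pool, "i2"),
      pool = NULL
    ) %>%
    tidyr::pivot_wider(
      names_from = "design",
      values_from = c("k", "pooled", "se", "tau2", "i2"),
      names_glue = "{.value}_{tolower(design)}"
    )

  # make sure both design column sets exist even if one design is absent
  for (col in paste0(rep(c("k_", "pooled_", "se_", "tau2_", "i2_"), each = 2),
                     c("sat", "sac"))) {
    if (!col %in% names(by_design)) by_design[[col]] <- NA_real_
  }

  zcrit <- qnorm(1 - alpha / 2)
  cmp <- by_design %>%
    mutate(
      comparable = !is.na(.data$k_sat) & !is.na(.data$k_sac),
      d = .data$pooled_sat - .data$pooled_sac,
      se_d = sqrt(.data$se_sat^2 + .data$se_sac^2),
      ci_low = .data$d - Z95 * .data$se_d,
      ci_high = .data$d + Z95 * .data$se_d,
      z = .data$d / .data$se_d,
      p = 2 * pnorm(-abs(.data$z)),
      direction = dplyr::case_when(
        !.data$comparable ~ NA_character_,
        .data$d > 0 ~ "SAT-higher",
        .data$d < 0 ~ "SAC-higher",
        TRUE ~ "tied"
      ),
      significance = dplyr::case_when(
        !.data$comparable ~ NA_character_,
        abs(.data$z) > zcrit & .data$d > 0 ~ "sig-SAT-higher",
        abs(.data$z) > zcrit & .data$d < 0 ~ "sig-SAC-higher",
        TRUE ~ "not-significant"
      )
    ) %>%
    arrange(.data$review_id)

  n_skip <- sum(!cmp$comparable)
  if (n_skip > 0) {
    inform(paste0(
      n_skip, " review(s) lack one design subgroup and are excluded from ",
      "between-design comparison: ",
      paste(cmp$review_id[!cmp$comparable], collapse = ", ")
    ))
  }
  structure(cmp, class = c("design_comparison", class(cmp)),
            alpha = alpha)
}

#' Pool within-review risk differences across reviews
#'
#' The review-level risk differences and their standard errors are
#' meta-analysed by generic inverse-variance DerSimonian-Laird
#' random-effects pooling, and the per-review directions and
#' significance classes are tallied. Only comparable reviews (both
#' designs present) enter.
#'
#' @param comparisons A `"design_comparison"` tibble from
#'   [compare_designs()].
#' @return An object of class `"cross_review"`: a list with `rd` (a
#'   [pool_dl()] `"meta_pool"` over the review-level differences),
#'   `rankings` (counts of `SAT-higher` / `SAC-higher` / `tied`),
#'   `sig_counts` (counts per significance class), and `n_reviews`.
#' @examples
#' sim <- simulate_evidence(sim_config(seed = 1))
#' pool_risk_differences(compare_designs(sim$evidence))
#' @export
pool_risk_differences <- function(comparisons) {
  cmp <- dplyr::filter(comparisons, .data$comparable)
  if (nrow(cmp) == 0) {
    abort("no comparable reviews (need >= 1 with both designs)",
          class = "satmeta_domain_error")
  }
  structure(
    list(
      rd = pool_dl(cmp$d, cmp$se_d^2),
      rankings = tally_rankings(cmp),
      sig_counts = cmp %>% count(.data$significance, name = "n_reviews"),
      n_reviews = nrow(cmp)
    ),
    class = "cross_review"
  )
}

#' Tally review-level directions
#'
#' @param comparisons A `"design_comparison"` tibble (only comparable
#'   rows are counted).
#' @return A tibble with columns `n_sat_higher`, `n_sac_higher`,
#'   `n_tied`; the three sum to the number of comparable reviews.
#' @export
tally_rankings <- function(comparisons) {
  dir <- comparisons$direction
  if (!is.null(comparisons$comparable)) dir <- dir[comparisons$comparable]
  dir <- dir[!is.na(dir)]
  tibble(
    n_sat_higher = sum(dir == "SAT-higher"),
    n_sac_higher = sum(dir == "SAC-higher"),
    n_tied = sum(dir == "tied")
  )
}

#' @export
print.cross_review <- function(x, ...) {
  cat(sprintf("<cross_review: %d reviews>\n", x$n_reviews))
  cat(sprintf(
    "  pooled risk difference (SAT - SAC): %.4f, 95%% CI [%.4f, %.4f], p = %.4g\n",
    x$rd$pooled, x$rd$ci_low, x$rd$ci_high, x$rd$p_z
  ))
  cat(sprintf(
    "  heterogeneity of differences: Q = %.3f, tau2 = %.5f, I2 = %s\n",
    x$rd$Q, x$rd$tau2,
    if (is.na(x$rd$i2)) "undefined" else sprintf("%.2f%%", x$rd$i2)
  ))
  cat(sprintf(
    "  rankings: %d SAT-higher / %d SAC-higher / %d tied\n",
    x$rankings$n_sat_higher, x$rankings$n_sac_higher, x$rankings$n_tied
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cross_review <- function(x, ...) tidy(x$rd, ...)

#' @exportS3Method generics::glance
glance.cross_review <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_reviews = x$n_reviews),
    tidy(x$rd)[c("pooled", "se", "ci_low", "ci_high", "p_z", "Q", "tau2", "i2")],
    x$rankings
  )
}
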