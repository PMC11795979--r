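#' Plot methods for pipeline results
#'
#' `autoplot()` on a `"design_comparison"` draws a forest-style plot of
#' the per-review SAT-minus-SAC risk differences with their 95%
#' intervals (positive values mean the trials ran higher);
#' `plot_pooled_proportions()` shows the two pooled subgroup proportions
#' per review side by side; `autoplot()` on a `"satmeta_sensitivity"`
#' draws the before/after I-squared scatter, one point per review and
#' design, with groups reduced to a single study (undefined I-squared
#' afterwards) pinned to the axis and marked.
#'
#' @param object A `"design_comparison"` tibble or
#'   `"satmeta_sensitivity"` object.
#' @param ... Unused, for method consistency.
#' @return A `ggplot` object.
#' @name satmeta-plots
NULL

#' @rdname satmeta-plots
#' @exportS3Method ggplot2::autoplot
autoplot.design_comparison <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$comparable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$review_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high,
                   colour = .data$significance)
    ) +
    ggplot2::labs(
      x = "Risk difference (SAT - SAC), 95% CI",
      y = NULL, colour = NULL,
      title = "Within-review risk differences by study design"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname satmeta-plots
#' @param comparisons A `"design_comparison"` tibble.
#' @export
plot_pooled_proportions <- function(comparisons) {
  df <- as_tibble(comparisons) %>%
    select("review_id", SAT_pooled = "pooled_sat", SAC_pooled = "pooled_sac",
           SAT_se = "se_sat", SAC_se = "se_sac") %>%
    tidyr::pivot_longer(
      -"review_id",
      names_to = c("design", ".value"), names_sep = "_"
    ) %>%
    filter(!is.na(.data$pooled)) %>%
    mutate(ci_low = pmax(0, .data$pooled - Z95 * .data$se),
           ci_high = pmin(1, .data$pooled + Z95 * .data$se))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pooled, y = .data$review_id,
                                   colour = .data$design)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::labs(
      x = "Pooled event proportion, 95% CI", y = NULL, colour = NULL,
      title = "Pooled proportions by design within each review"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname satmeta-plots
#' @exportS3Method ggplot2::autoplot
autoplot.satmeta_sensitivity <- function(object, ...) {
  df <- object$i2_deltas %>%
    filter(!is.na(.data$i2_before)) %>%
    mutate(
      single_after = is.na(.data$i2_after),
      i2_after_plot = tidyr::replace_na(.data$i2_after, 0)
    )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$i2_before, y = .data$i2_after_plot,
                 colour = .data$design, shape = .data$single_after)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 4),
      labels = c(`FALSE` = "both defined",
                 `TRUE` = "single study remaining")
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(
      x = expression(I^2 ~ "before exclusion (%)"),
      y = expression(I^2 ~ "after exclusion (%)"),
      colour = NULL, shape = NULL,
      title = "Heterogeneity before and after removing flagged studies"
    ) +
    ggplot2::theme_minimal()
}
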