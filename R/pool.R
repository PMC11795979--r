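#' Fixed-effect and DerSimonian-Laird random-effects pooling
#'
#' Generic inverse-variance pooling of study effects given as
#' (estimate, variance) pairs, on whatever scale the estimates live on
#' (here usually event proportions or risk differences).
#' `pool_fixed()` weights each study by `1/v`; `pool_dl()` additionally
#' estimates the between-study variance \eqn{\tau^2} by the
#' DerSimonian-Laird moment estimator and re-weights by
#' `1/(v + tau2)`.
#'
#' Heterogeneity is summarised by Cochran's Q (computed about the
#' fixed-effect mean), \eqn{\tau^2 = \max(0, (Q - df)/C)} with
#' \eqn{C = \sum w_i - \sum w_i^2 / \sum w_i}, and
#' \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100}. For a single study
#' \eqn{I^2} is undefined and reported as `NA`.
#'
#' Confidence intervals are Wald-type, `pooled +/- 1.959964 * se`.
#' `p_z` is the two-sided normal p-value for `pooled = 0`; it is
#' meaningful on a difference scale, not for raw proportions.
#'
#' @param y Numeric vector of study effect estimates.
#' @param v Numeric vector of within-study variances, same length as `y`.
#'   All must be positive (a single study with `v = 0` is tolerated:
#'   the "estimate" is passed through with a zero-width interval).
#'
#' @return An object of class `"meta_pool"`: a list with elements
#'   `k`, `pooled`, `se`, `ci_low`, `ci_high`, `Q`, `df`, `tau2`, `i2`,
#'   `p_z` and `method`. Use [tidy()] to get a one-row tibble.
#'
#' @examples
#' pool_dl(c(0.2, 0.5, 0.8), c(0.01, 0.01, 0.01))
#' tidy(pool_fixed(c(0.1, 0.2), c(0.004, 0.009)))
#' @export
pool_dl <- function(y, v) {
  new_meta_pool(dl_stats(check_effects(y, v)$y, v), method = "DL")
}

#' @rdname pool_dl
#' @export
pool_fixed <- function(y, v) {
  check_effects(y, v)
  s <- fe_stats(y, v)
  new_meta_pool(
    c(s, list(tau2 = 0, i2 = i_squared(s$Q, s$df))),
    method = "FE"
  )
}

check_effects <- function(y, v) {
  if (length(y) == 0L) {
    abort("at least one study effect is required", class = "satmeta_domain_error")
  }
  if (length(y) != length(v)) {
    abort("`y` and `v` must have the same length", class = "satmeta_domain_error")
  }
  if (anyNA(y) || anyNA(v)) {
    abort("study effects must not contain NA", class = "satmeta_domain_error")
  }
  if (any(v < 0) || (length(v) > 1L && any(v <= 0))) {
    abort(
      "all within-study variances must be positive for k >= 2 pooling",
      class = "satmeta_domain_error"
    )
  }
  list(y = y, v = v)
}

# inverse-variance fixed-effect core; assumes inputs checked
fe_stats <- function(y, v) {
  k <- length(y)
  if (k == 1L) {
    se <- sqrt(v)
    return(list(
      k = 1L, pooled = y, se = se,
      ci_low = y - Z95 * se, ci_high = y + Z95 * se,
      Q = 0, df = 0L,
      p_z = if (se > 0) 2 * pnorm(-abs(y / se)) else as.numeric(y == 0)
    ))
  }
  w <- 1 / v
  sw <- sum(w)
  pooled <- sum(w * y) / sw
  se <- sqrt(1 / sw)
  list(
    k = k, pooled = pooled, se = se,
    ci_low = pooled - Z95 * se, ci_high = pooled + Z95 * se,
    Q = sum(w * (y - pooled)^2), df = k - 1L,
    p_z = 2 * pnorm(-abs(pooled / se))
  )
}

# DerSimonian-Laird moment estimator built on the fixed-effect Q
dl_stats <- function(y, v) {
  k <- length(y)
  fe <- fe_stats(y, v)
  if (k == 1L) {
    return(c(fe[c("k", "pooled", "se", "ci_low", "ci_high", "Q", "df", "p_z")],
             list(tau2 = 0, i2 = NA_real_)))
  }
  w <- 1 / v
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (fe$Q - (k - 1)) / C)
  ws <- 1 / (v + tau2)
  pooled <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(
    k = k, pooled = pooled, se = se,
    ci_low = pooled - Z95 * se, ci_high = pooled + Z95 * se,
    Q = fe$Q, df = k - 1L, tau2 = tau2,
    i2 = i_squared(fe$Q, k - 1L),
    p_z = 2 * pnorm(-abs(pooled / se))
  )
}

new_meta_pool <- function(stats, method) {
  structure(
    stats[c("k", "pooled", "se", "ci_low", "ci_high",
            "Q", "df", "tau2", "i2", "p_z")],
    method = method,
    class = "meta_pool"
  )
}

#' @export
print.meta_pool <- function(x, ...) {
  cat(sprintf(
    "<meta_pool: %s, k = %d>\n  pooled = %.4f (se %.4f), 95%% CI [%.4f, %.4f]\n  Q = %.3f (df %d), tau2 = %.5f, I2 = %s\n",
    attr(x, "method"), x$k, x$pooled, x$se, x$ci_low, x$ci_high,
    x$Q, x$df, x$tau2,
    if (is.na(x$i2)) "undefined (k = 1)" else sprintf("%.2f%%", x$i2)
  ))
  invisible(x)
}

#' I-squared heterogeneity statistic
#'
#' Proportion of total variability in study effects attributable to
#' between-study heterogeneity, `max(0, (Q - df)/Q) * 100`, as a
#' percentage. Undefined (`NA`) when `df = 0`, i.e. for a single study:
#' a one-study group carries no information about inconsistency.
#'
#' @param Q Cochran's heterogeneity statistic (nonnegative).
#' @param df Degrees of freedom, `k - 1`.
#' @return Percentage in `[0, 100]`, or `NA` when `df = 0`.
#' @examples
#' i_squared(18, 2) # 88.89
#' i_squared(3, 3)  # 0
#' @export
i_squared <- function(Q, df) {
  if (any(Q < 0, na.rm = TRUE)) {
    abort("`Q` must be nonnegative", class = "satmeta_domain_error")
  }
  out <- ifelse(df == 0L | Q == 0, 0, pmax(0, (Q - df) / Q) * 100)
  out[df == 0L] <- NA_real_
  out
}

#' Classify an I-squared value against the substantial-heterogeneity bound
#'
#' Heterogeneity of at least 50% is classed as substantial (closed bound).
#' `NA` inputs (single-study groups) are classed `"undefined"`.
#'
#' @param i2 Numeric vector of I-squared percentages in `[0, 100]`, `NA`
#'   allowed.
#' @return Character vector with levels `"substantial"`,
#'   `"not-substantial"`, `"undefined"`.
#' @export
classify_heterogeneity <- function(i2) {
  dplyr::case_when(
    is.na(i2) ~ "undefined",
    i2 >= 50 ~ "substantial",
    TRUE ~ "not-substantial"
  )
}

#' @exportS3Method generics::tidy
tidy.meta_pool <- function(x, ...) {
  tibble(
    k = x$k, pooled = x$pooled, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high,
    Q = x$Q, df = x$df, tau2 = x$tau2, i2 = x$i2, p_z = x$p_z,
    method = attr(x, "method")
  )
}

#' @exportS3Method generics::glance
glance.meta_pool <- function(x, ...) tidy(x, ...)
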