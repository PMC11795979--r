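#' Wilcoxon signed-rank test with the min-sum convention
#'
#' Paired comparison of two samples (here: per-review I-squared values
#' for the two designs). Differences `x - y` are formed, exact zeros are
#' dropped, absolute differences are ranked with average ranks for ties,
#' and the statistic is `W = min(W+, W-)`, the smaller of the two signed
#' rank sums.
#'
#' Two p-value routes are available:
#'
#' * `"exact"` — the full null distribution of `W+` over all `2^n` sign
#'   assignments, computed by integer-weight convolution (so tied, i.e.
#'   half-integer, ranks are handled exactly); two-sided p is
#'   `min(1, 2 * P(W+ <= W))` by symmetry. Supported for `n <= 25`
#'   non-zero pairs.
#' * `"normal"` — `Z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` with no
#'   continuity correction and, by default, no tie correction; this is
#'   the classical large-sample form in which `W = min` makes `Z` always
#'   non-positive. Set `tie_correction = TRUE` to subtract the usual
#'   `sum(t^3 - t)/48` tie term from the variance.
#'
#' `"auto"` uses the exact route when `n <= 25`, the normal
#' approximation otherwise.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param tie_correction Apply the tie-corrected variance in the normal
#'   approximation (default `FALSE`).
#' @return An object of class `"rank_test"`: list with
#'   `statistic_name` (`"W"`), `statistic`, `z` (normal mode only),
#'   `p`, `n_used` (non-zero pairs), `method`.
#' @examples
#' wilcoxon_signed_rank(c(5, 3, 8, 1), c(1, 2, 4, 0), mode = "exact")
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "normal"),
                                 tie_correction = FALSE) {
  mode <- arg_match(mode)
  if (length(x) != length(y) || length(x) == 0) {
    abort("`x` and `y` must be nonempty paired vectors of equal length",
          class = "satmeta_domain_error")
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    abort("all paired differences are zero; signed-rank test is degenerate",
          class = "satmeta_degenerate_error")
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  tied <- anyDuplicated(r) > 0

  if (mode == "auto") mode <- if (n <= 25) "exact" else "normal"

  if (mode == "exact") {
    if (n > 25) {
      abort("exact signed-rank p only supported for n <= 25 non-zero pairs",
            class = "satmeta_domain_error")
    }
    p <- if (tied) {
      signed_rank_cdf_tied(W, r)
    } else {
      psignrank(W, n)
    }
    p <- min(1, 2 * p)
    zval <- NA_real_
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    v <- n * (n + 1) * (2 * n + 1) / 24
    if (tie_correction && tied) {
      tt <- table(r)
      v <- v - sum(tt^3 - tt) / 48
    }
    zval <- (W - mu) / sqrt(v)
    p <- 2 * pnorm(-abs(zval))
    method <- "normal-approx"
  }

  new_rank_test("W", W, zval, p, n, method)
}

# P(W+ <= w) under the signed-rank null with (possibly tied) ranks r,
# by convolution over the 2^n sign assignments with integer weights 2*r
signed_rank_cdf_tied <- function(w, r) {
  u <- as.integer(round(2 * r))
  f <- 1 # counts over support 0..sum(u) of 2*W+
  for (ui in u) {
    g <- c(f, rep(0, ui))
    g[(ui + 1):(ui + length(f))] <- g[(ui + 1):(ui + length(f))] + f
    f <- g
  }
  f <- f / 2^length(u)
  sum(f[seq_len(floor(round(2 * w, 8)) + 1)])
}

#' Mann-Whitney U test with the min-U convention
#'
#' Unpaired comparison of two samples. Ranks are assigned over the
#' combined sample with average ranks for ties, `U_a` and `U_b` are the
#' two rank-sum statistics, and `U = min(U_a, U_b)` is reported.
#'
#' For untied samples with `n1 * n2 <= 400` the two-sided p-value is
#' exact, `min(1, 2 * P(U <= u))` from the exact null distribution of U.
#' Otherwise the normal approximation is used with tie-corrected
#' variance and a 0.5 continuity correction:
#' `Z = (U - n1 n2 / 2 + 0.5) / sqrt(var)`. Forcing `mode = "exact"` on
#' tied data falls back to the approximation with a warning, since no
#' exact tied distribution is tabulated.
#'
#' @param a,b Numeric sample vectors, both nonempty.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return An object of class `"rank_test"` with `statistic_name` `"U"`,
#'   `statistic`, `z` (approximation only), `p`, `n_used` (c(n1, n2)),
#'   `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4), mode = "exact") # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- arg_match(mode)
  n1 <- length(a)
  n2 <- length(b)
  if (n1 == 0 || n2 == 0) {
    abort("both samples must be nonempty", class = "satmeta_domain_error")
  }
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_b <- n1 * n2 - u_a
  U <- min(u_a, u_b)
  tied <- anyDuplicated(r) > 0

  exact_ok <- !tied && n1 * n2 <= 400
  if (mode == "auto") mode <- if (exact_ok) "exact" else "normal"
  if (mode == "exact" && !exact_ok) {
    warn(paste0(
      "exact Mann-Whitney p requires untied samples with n1*n2 <= 400; ",
      "using the normal approximation"
    ))
    mode <- "normal"
  }

  if (mode == "exact") {
    p <- min(1, 2 * pwilcox(U, n1, n2))
    zval <- NA_real_
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tt <- table(r)
    v <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (v <= 0) {
      # all observations identical: no evidence against the null
      zval <- 0
      p <- 1
    } else {
      # continuity correction, not allowed to carry U past the null mean
      zval <- min(0, U - mu + 0.5) / sqrt(v)
      p <- min(1, 2 * pnorm(-abs(zval)))
    }
    method <- "normal-approx"
  }

  new_rank_test("U", U, zval, p, c(n1, n2), method)
}

new_rank_test <- function(statistic_name, statistic, z, p, n_used, method) {
  structure(
    list(statistic_name = statistic_name, statistic = statistic,
         z = z, p = p, n_used = n_used, method = method),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf(
    "<rank_test: %s = %g (%s), n = %s>\n  %sp = %.5g\n",
    x$statistic_name, x$statistic, x$method,
    paste(x$n_used, collapse = "/"),
    if (!is.na(x$z)) sprintf("Z = %.4f, ", x$z) else "",
    x$p
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rank_test <- function(x, ...) {
  tibble(
    statistic_name = x$statistic_name,
    statistic = x$statistic,
    z = x$z,
    p = x$p,
    n1 = x$n_used[1],
    n2 = if (length(x$n_used) > 1) x$n_used[2] else NA_integer_,
    method = x$method
  )
}
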