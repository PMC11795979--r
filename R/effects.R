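#' Convert study records to proportion-scale effects
#'
#' Every pooling step in the pipeline consumes an effect estimate `y`
#' and within-study variance `v` on the natural proportion scale (not
#' logit or arcsine): the across-review comparison is a risk difference
#' of pooled proportions, and CI-mode inputs only carry natural-scale
#' standard errors.
#'
#' Counts mode uses `y = events/n`, `v = y(1-y)/n`. Boundary studies
#' (zero or all events) would get zero variance and hence infinite
#' inverse-variance weight; the default `correction = "add-half"`
#' replaces them with `y = (events + 0.5)/(n + 1)`,
#' `v = y(1-y)/(n + 1)`. `correction = "none"` leaves them untouched
#' (yielding `v = 0`, flagged non-poolable).
#'
#' CI mode takes `y = estimate` and recovers the standard error from the
#' reported 95% interval width: `se = (ci_high - ci_low)/(2 * 1.959964)`.
#' A zero-width interval gives `v = 0` and is flagged non-poolable; it
#' only ever enters a pooled result alone (`k = 1`).
#'
#' @param data A validated evidence-base tibble (see
#'   [validate_evidence()]).
#' @param events,n Integer vectors for the vector interface.
#' @param estimate,ci_low,ci_high Proportion vectors for the vector
#'   interface.
#' @param correction Boundary-count policy, `"add-half"` (default) or
#'   `"none"`.
#' @return `study_effects()` returns `data` with columns `y`, `v`,
#'   `poolable` (logical, `v > 0`) and `corrected` (logical, boundary
#'   correction applied) appended. The vector helpers return a tibble
#'   with columns `y` and `v`.
#' @examples
#' effect_from_counts(5, 10)           # y 0.5, v 0.025
#' effect_from_counts(0, 10)           # corrected: y 0.5/11
#' effect_from_ci(0.5, 0.4, 0.6)       # se 0.051021
#' @export
study_effects <- function(data, correction = c("add-half", "none")) {
  correction <- arg_match(correction)
  data <- validate_evidence(data)
  counts_mode <- !is.na(data$events) & !is.na(data$n)
  y <- v <- rep(NA_real_, nrow(data))
  corrected <- rep(FALSE, nrow(data))
  if (any(counts_mode)) {
    fc <- effect_from_counts(data$events[counts_mode], data$n[counts_mode],
                             correction = correction)
    y[counts_mode] <- fc$y
    v[counts_mode] <- fc$v
    corrected[counts_mode] <- fc$corrected
  }
  if (any(!counts_mode)) {
    fi <- effect_from_ci(data$estimate[!counts_mode],
                         data$ci_low[!counts_mode],
                         data$ci_high[!counts_mode])
    y[!counts_mode] <- fi$y
    v[!counts_mode] <- fi$v
  }
  data %>%
    mutate(y = y, v = v, poolable = v > 0, corrected = corrected)
}

#' @rdname study_effects
#' @export
effect_from_counts <- function(events, n, correction = c("add-half", "none")) {
  correction <- arg_match(correction)
  if (any(is.na(events)) || any(is.na(n)) || any(n < 1) ||
      any(events < 0) || any(events > n)) {
    abort("counts must satisfy 0 <= events <= n with n >= 1",
          class = "satmeta_domain_error")
  }
  boundary <- events == 0 | events == n
  if (correction == "add-half") {
    e <- ifelse(boundary, events + 0.5, events)
    m <- ifelse(boundary, n + 1, n)
  } else {
    e <- events
    m <- n
    boundary <- rep(FALSE, length(events))
  }
  y <- e / m
  tibble(y = y, v = y * (1 - y) / m, corrected = boundary)
}

#' @rdname study_effects
#' @export
effect_from_ci <- function(estimate, ci_low, ci_high) {
  if (any(is.na(estimate)) || any(is.na(ci_low)) || any(is.na(ci_high))) {
    abort("estimate and CI bounds must not be NA",
          class = "satmeta_domain_error")
  }
  if (any(ci_low > estimate) || any(estimate > ci_high)) {
    abort("CI bounds must satisfy ci_low <= estimate <= ci_high",
          class = "satmeta_validation_error")
  }
  se <- (ci_high - ci_low) / (2 * Z95)
  tibble(y = estimate, v = se^2)
}
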