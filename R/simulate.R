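#' Review shapes matching the 13-review evidence base
#'
#' Subgroup sizes (number of SATs, number of SACs) for the thirteen
#' systematic reviews the pipeline was designed around; reviews
#' contribute between 1 and 33 trials and between 1 and 18 cohorts, so
#' recovery simulations run on the real data shape, including its
#' single-study subgroups.
#'
#' @return A tibble with columns `review_id`, `k_sat`, `k_sac`
#'   (13 rows).
#' @export
table1_shapes <- function() {
  tibble(
    review_id = sprintf("R%02d", 1:13),
    k_sat = c(2L, 7L, 1L, 5L, 7L, 1L, 1L, 2L, 2L, 33L, 2L, 9L, 3L),
    k_sac = c(1L, 7L, 15L, 7L, 1L, 8L, 2L, 18L, 13L, 16L, 4L, 1L, 2L)
  )
}

#' Simulation configuration
#'
#' Declares the generative model for a synthetic evidence base. For
#' review `j`, a baseline proportion `p_j` is drawn uniformly from
#' `baseline_range`. Study `i` of design `d` then has true log-odds
#' `logit(p_j) + offset_d + eps`, with `eps ~ N(0, tau_logit^2)`
#' between-study heterogeneity. The SAT offset is zero; the SAC offset
#' is chosen so that at the review baseline the true SAT-minus-SAC risk
#' difference equals `delta_rd` (the estimand the pipeline's pooled
#' risk difference targets — negative values make cohorts run higher).
#' Injecting on the log-odds scale keeps every true proportion inside
#' (0, 1) without clamping.
#'
#' A fraction `outlier_fraction` of studies is made clinically
#' heterogeneous: an extra `outlier_shift_logit` is added to their
#' log-odds and their `clin_het_flag` is set, giving the sensitivity
#' analysis a ground truth to recover. Events are drawn
#' `Binomial(n, p_true)` with `n` uniform on `n_range`.
#'
#' @param shapes `"table1"` for the 13-review preset, or a data frame
#'   with columns `k_sat`, `k_sac` (and optionally `review_id`).
#' @param baseline_range Interval of review baseline proportions.
#' @param tau_logit Between-study SD on the log-odds scale (per design).
#' @param delta_rd True SAT-minus-SAC risk difference at the review
#'   baseline.
#' @param n_range Integer interval of per-study sample sizes.
#' @param outlier_fraction Fraction of studies flagged clinically
#'   heterogeneous.
#' @param outlier_shift_logit Extra log-odds shift given to flagged
#'   studies.
#' @param seed Integer seed; every draw in [simulate_evidence()] flows
#'   from it.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(delta_rd = -0.07, seed = 42)
#' @export
sim_config <- function(shapes = "table1",
                       baseline_range = c(0.2, 0.7),
                       tau_logit = 0.3,
                       delta_rd = 0,
                       n_range = c(20L, 200L),
                       outlier_fraction = 0,
                       outlier_shift_logit = 1,
                       seed = NULL) {
  if (is.character(shapes) && identical(shapes, "table1")) {
    shapes <- table1_shapes()
  } else if (is.data.frame(shapes)) {
    if (!all(c("k_sat", "k_sac") %in% names(shapes))) {
      abort("`shapes` needs columns k_sat and k_sac",
            class = "satmeta_config_error")
    }
    shapes <- as_tibble(shapes)
    if (!"review_id" %in% names(shapes)) {
      shapes$review_id <- sprintf("R%02d", seq_len(nrow(shapes)))
    }
  } else {
    abort("`shapes` must be \"table1\" or a data frame",
          class = "satmeta_config_error")
  }
  if (nrow(shapes) == 0 || any(shapes$k_sat < 1) || any(shapes$k_sac < 1)) {
    abort("every review needs at least one study of each design",
          class = "satmeta_config_error")
  }
  stopifnot(
    length(baseline_range) == 2, baseline_range[1] <= baseline_range[2],
    length(n_range) == 2, n_range[1] >= 1, n_range[1] <= n_range[2],
    tau_logit >= 0, outlier_fraction >= 0, outlier_fraction <= 1
  )
  if (any(baseline_range <= 0) || any(baseline_range >= 1)) {
    abort("baseline proportions must lie strictly inside (0, 1)",
          class = "satmeta_config_error")
  }
  # the SAC arm sits at p_j - delta_rd; must stay inside (0, 1)
  sac_range <- baseline_range - delta_rd
  if (any(sac_range <= 0) || any(sac_range >= 1)) {
    abort(paste0(
      "delta_rd = ", delta_rd, " pushes the SAC true proportion outside ",
      "(0, 1) for baselines in [", baseline_range[1], ", ",
      baseline_range[2], "]"
    ), class = "satmeta_config_error")
  }
  structure(
    list(
      shapes = shapes, n_reviews = nrow(shapes),
      baseline_range = as.numeric(baseline_range),
      tau_logit = tau_logit, delta_rd = delta_rd,
      n_range = as.integer(n_range),
      outlier_fraction = outlier_fraction,
      outlier_shift_logit = outlier_shift_logit,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' Log-odds offset producing a target risk difference
#'
#' Returns the shift on the log-odds scale that moves `baseline` to
#' `baseline + delta_rd`: `logit(baseline + delta_rd) - logit(baseline)`.
#'
#' @param baseline Baseline proportion in (0, 1).
#' @param delta_rd Risk difference; `baseline + delta_rd` must stay in
#'   (0, 1).
#' @return Log-odds offset (numeric).
#' @examples
#' logit_offset_for_rd(0.5, 0.2310) # ~= 1
#' @export
logit_offset_for_rd <- function(baseline, delta_rd) {
  target <- baseline + delta_rd
  if (any(baseline <= 0) || any(baseline >= 1) ||
      any(target <= 0) || any(target >= 1)) {
    abort("baseline and baseline + delta_rd must lie strictly inside (0, 1)",
          class = "satmeta_domain_error")
  }
  qlogis(target) - qlogis(baseline)
}

#' Simulate a synthetic evidence base with recorded ground truth
#'
#' Draws an evidence base from the generative model declared in a
#' [sim_config()] and records everything needed to judge recovery: the
#' per-review baselines, each study's true proportion, the injected
#' design effect and the outlier flags (which are copied verbatim into
#' `clin_het_flag`). Identical config and seed give identical output.
#'
#' @param config A `"sim_config"` object.
#' @return A list of class `"satmeta_sim"` with elements `evidence`
#'   (a validated evidence tibble, counts mode), `truth` (tibble with
#'   `review_id`, `study_id`, `design`, `baseline`, `p_true`,
#'   `outlier`) and `config`.
#' @examples
#' sim <- simulate_evidence(sim_config(seed = 7))
#' dplyr::count(sim$evidence, design)
#' @export
simulate_evidence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  run <- function() {
    per_review <- purrr::pmap(
      config$shapes,
      function(review_id, k_sat, k_sac, ...) {
        p_j <- runif(1, config$baseline_range[1], config$baseline_range[2])
        offset_sac <- logit_offset_for_rd(p_j, -config$delta_rd)
        k <- k_sat + k_sac
        design <- rep(c("SAT", "SAC"), c(k_sat, k_sac))
        offs <- ifelse(design == "SAC", offset_sac, 0)
        outlier <- runif(k) < config$outlier_fraction
        lo <- qlogis(p_j) + offs + rnorm(k, 0, config$tau_logit) +
          outlier * config$outlier_shift_logit
        p_true <- plogis(lo)
        sizes <- seq.int(config$n_range[1], config$n_range[2])
        n <- sizes[sample.int(length(sizes), k, replace = TRUE)]
        tibble(
          review_id = review_id,
          study_id = sprintf("%s_%s_%02d", review_id, design,
                             c(seq_len(k_sat), seq_len(k_sac))),
          design = design,
          events = rbinom(k, n, p_true),
          n = n,
          estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          clin_het_flag = outlier,
          outcome = "response",
          baseline = p_j,
          p_true = p_true
        )
      }
    ) %>% bind_rows()
    per_review
  }
  draws <- if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())

  evidence <- validate_evidence(
    draws[, c("review_id", "study_id", "design", "events", "n",
              "estimate", "ci_low", "ci_high", "clin_het_flag", "outcome")]
  )
  truth <- draws %>%
    select("review_id", "study_id", "design", "baseline", "p_true",
           outlier = "clin_het_flag") %>%
    mutate(delta_rd = config$delta_rd)
  structure(list(evidence = evidence, truth = truth, config = config),
            class = "satmeta_sim")
}

#' Write a simulated truth table with its configuration header
#'
#' The ground-truth table is written as CSV preceded by commented YAML
#' lines echoing the generating configuration, so a truth file is fully
#' self-describing. [read_truth()] skips the header.
#'
#' @param sim A `"satmeta_sim"` object.
#' @param path Output path.
#' @return `sim`, invisibly.
#' @export
write_truth <- function(sim, path) {
  stopifnot(inherits(sim, "satmeta_sim"))
  cfg <- sim$config
  hdr <- c(
    "# config:",
    sprintf("#   n_reviews: %d", cfg$n_reviews),
    sprintf("#   baseline_range: [%g, %g]",
            cfg$baseline_range[1], cfg$baseline_range[2]),
    sprintf("#   tau_logit: %g", cfg$tau_logit),
    sprintf("#   delta_rd: %g", cfg$delta_rd),
    sprintf("#   n_range: [%d, %d]", cfg$n_range[1], cfg$n_range[2]),
    sprintf("#   outlier_fraction: %g", cfg$outlier_fraction),
    sprintf("#   outlier_shift_logit: %g", cfg$outlier_shift_logit),
    sprintf("#   seed: %s", if (is.null(cfg$seed)) "null" else cfg$seed)
  )
  writeLines(hdr, path)
  readr::write_csv(sim$truth, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(sim)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
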