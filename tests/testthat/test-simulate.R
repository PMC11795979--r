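test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(delta_rd = -0.05, outlier_fraction = 0.1, seed = 77)
  a <- simulate_evidence(cfg)
  b <- simulate_evidence(cfg)
  expect_identical(a$evidence, b$evidence)
  expect_identical(a$truth, b$truth)
  c <- simulate_evidence(sim_config(delta_rd = -0.05, outlier_fraction = 0.1,
                                    seed = 78))
  expect_false(identical(a$evidence, c$evidence))
})

test_that("the 13-review preset reproduces the published subgroup sizes", {
  sim <- simulate_evidence(sim_config(seed = 1))
  counts <- sim$evidence %>%
    dplyr::count(review_id, design) %>%
    tidyr::pivot_wider(names_from = design, values_from = n)
  shapes <- table1_shapes()
  expect_equal(nrow(counts), 13)
  expect_equal(counts$SAT, shapes$k_sat)
  expect_equal(counts$SAC, shapes$k_sac)
  # largest review: 33 trials, 16 cohorts
  expect_equal(counts$SAT[counts$review_id == "R10"], 33L)
  expect_equal(counts$SAC[counts$review_id == "R10"], 16L)
  expect_equal(range(shapes$k_sat), c(1L, 33L))
  expect_equal(range(shapes$k_sac), c(1L, 18L))
})

test_that("a degenerate configuration collapses to one proportion per review", {
  cfg <- sim_config(tau_logit = 0, delta_rd = 0, outlier_fraction = 0,
                    seed = 4)
  sim <- simulate_evidence(cfg)
  per_review <- sim$truth %>%
    dplyr::group_by(review_id) %>%
    dplyr::summarise(n_p = dplyr::n_distinct(p_true),
                     off_baseline = max(abs(p_true - baseline)))
  expect_true(all(per_review$n_p == 1))
  expect_true(all(per_review$off_baseline < 1e-12))
})

test_that("outlier flags in the truth match the evidence flags", {
  sim <- simulate_evidence(sim_config(outlier_fraction = 0.25, seed = 9))
  expect_equal(sim$truth$outlier, sim$evidence$clin_het_flag)
  expect_gt(sum(sim$truth$outlier), 0)
  # outliers sit above their review/design peers on the logit scale
  joined <- sim$truth
  expect_gt(
    mean(qlogis(joined$p_true[joined$outlier])) -
      mean(qlogis(joined$p_true[!joined$outlier])),
    0
  )
})

test_that("the logit offset hits the requested risk difference", {
  expect_equal(logit_offset_for_rd(0.5, 0), 0)
  expect_equal(logit_offset_for_rd(0.5, 0.2310), 1, tolerance = 1e-3)
  # inverse property: applying the offset lands exactly on baseline + rd
  for (p in c(0.2, 0.45, 0.7)) {
    for (rd in c(-0.15, 0, 0.1)) {
      off <- logit_offset_for_rd(p, rd)
      expect_equal(plogis(qlogis(p) + off), p + rd, tolerance = 1e-12)
    }
  }
  expect_error(logit_offset_for_rd(0.9, 0.2), class = "satmeta_domain_error")
})

test_that("configurations that push proportions out of range are refused", {
  expect_error(sim_config(delta_rd = 0.9), class = "satmeta_config_error")
  expect_error(sim_config(delta_rd = -0.5, baseline_range = c(0.5, 0.7)),
               class = "satmeta_config_error")
  expect_error(sim_config(baseline_range = c(0, 0.5)),
               class = "satmeta_config_error")
  expect_error(sim_config(shapes = tibble::tibble(k_sat = 0L, k_sac = 2L)),
               class = "satmeta_config_error")
  expect_error(sim_config(shapes = tibble::tibble(bad = 1)),
               class = "satmeta_config_error")
})

test_that("simulated proportions are centred on the design-specific truth", {
  # huge per-study samples squeeze the binomial noise away
  cfg <- sim_config(
    shapes = tibble::tibble(k_sat = rep(60L, 3), k_sac = rep(60L, 3)),
    tau_logit = 0, delta_rd = -0.07, n_range = c(99000L, 100000L),
    baseline_range = c(0.4, 0.5), seed = 6
  )
  sim <- simulate_evidence(cfg)
  eff <- study_effects(sim$evidence) %>%
    dplyr::left_join(sim$truth, by = c("review_id", "study_id", "design"))
  by_design <- eff %>%
    dplyr::group_by(review_id, design) %>%
    dplyr::summarise(mean_y = mean(y), baseline = baseline[1],
                     .groups = "drop")
  sat <- dplyr::filter(by_design, design == "SAT")
  sac <- dplyr::filter(by_design, design == "SAC")
  expect_equal(sat$mean_y, sat$baseline, tolerance = 5e-3)
  expect_equal(sac$mean_y, sac$baseline + 0.07, tolerance = 5e-3)
})

test_that("injected outliers inflate within-group dispersion", {
  qsum <- function(frac, seed) {
    sim <- simulate_evidence(sim_config(outlier_fraction = frac,
                                        outlier_shift_logit = 1.5,
                                        seed = seed))
    cmp <- suppressMessages(compare_designs(sim$evidence))
    sum(c(cmp$tau2_sat, cmp$tau2_sac), na.rm = TRUE)
  }
  seeds <- 301:315
  with_out <- sapply(seeds, function(s) qsum(0.2, s))
  without <- sapply(seeds, function(s) qsum(0, s))
  expect_gt(mean(with_out), mean(without))
})

test_that("truth files round-trip with their configuration header", {
  sim <- simulate_evidence(sim_config(outlier_fraction = 0.1, seed = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth(sim, path)
  header <- readLines(path, n = 2)
  expect_match(header[1], "^# config:")
  back <- read_truth(path)
  expect_equal(nrow(back), nrow(sim$truth))
  expect_equal(back$p_true, sim$truth$p_true, tolerance = 1e-12)
  expect_equal(back$outlier, sim$truth$outlier)
})
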