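test_that("a small mixed-mode evidence base loads, validates and round-trips", {
  ev <- tiny_evidence()
  out <- validate_evidence(ev)
  expect_s3_class(out, "tbl_df")
  expect_equal(nrow(out), 3)
  expect_equal(dplyr::n_distinct(out$review_id), 1)

  path <- withr::local_tempfile(fileext = ".csv")
  write_evidence(out, path)
  back <- read_evidence(path)
  expect_equal(as.data.frame(back), as.data.frame(out))
})

test_that("design labels are parsed case-insensitively and synonyms rejected", {
  ev <- tiny_evidence()
  ev$design <- c("sat", "Sat", "sac")
  expect_equal(validate_evidence(ev)$design, c("SAT", "SAT", "SAC"))
  ev$design[1] <- "trial"
  expect_error(validate_evidence(ev), class = "satmeta_validation_error")
  ev$design[1] <- "cohort"
  expect_error(validate_evidence(ev), class = "satmeta_validation_error")
})

test_that("validation names the offending rows for each invariant", {
  ev <- tiny_evidence()
  ev$events[1] <- 99L # events > n in row 1
  err <- expect_error(validate_evidence(ev), class = "satmeta_validation_error")
  expect_match(conditionMessage(err), "row\\(s\\) 1")

  both <- tiny_evidence()
  both$estimate[2] <- 0.4
  both$ci_low[2] <- 0.3
  both$ci_high[2] <- 0.5
  expect_error(validate_evidence(both), "row\\(s\\) 2",
               class = "satmeta_validation_error")

  neither <- tiny_evidence()
  neither$events[1] <- NA_integer_
  expect_error(validate_evidence(neither), "row\\(s\\) 1",
               class = "satmeta_validation_error")

  inverted <- tiny_evidence()
  inverted$ci_low[3] <- 0.7
  expect_error(validate_evidence(inverted), class = "satmeta_validation_error")
})

test_that("missing columns and empty files are format errors", {
  expect_error(validate_evidence(tiny_evidence()[, -3]),
               class = "satmeta_format_error")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), path)
  expect_error(read_evidence(path), class = "satmeta_format_error")
  expect_error(read_evidence(file.path(tempdir(), "no-such-file.csv")),
               class = "satmeta_format_error")
})

test_that("a review shaped like the largest included review keeps its subgroup sizes", {
  shapes <- table1_shapes()
  big <- shapes[shapes$k_sat == 33L, ]
  ev <- dplyr::bind_rows(
    counts_row(big$review_id, sprintf("t%02d", 1:33), "SAT",
               events = rep(5, 33), n = rep(20, 33)),
    counts_row(big$review_id, sprintf("c%02d", 1:16), "SAC",
               events = rep(6, 16), n = rep(20, 16))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_evidence(ev, path)
  counts <- dplyr::count(read_evidence(path), design)
  expect_equal(counts$n[counts$design == "SAT"], 33L)
  expect_equal(counts$n[counts$design == "SAC"], 16L)
})

test_that("counts-mode effects use y = e/n with boundary correction", {
  plain <- effect_from_counts(5, 10)
  expect_equal(plain$y, 0.5)
  expect_equal(plain$v, 0.025)
  expect_false(plain$corrected)

  zero <- effect_from_counts(0, 10)
  expect_equal(zero$y, 0.5 / 11)
  expect_equal(zero$v, (0.5 / 11) * (1 - 0.5 / 11) / 11)
  expect_true(zero$corrected)

  full <- effect_from_counts(10, 10)
  expect_equal(full$y, 10.5 / 11)
  expect_equal(full$y + zero$y, 1) # mirror symmetry of the correction
  expect_equal(full$v, zero$v)

  none <- effect_from_counts(0, 10, correction = "none")
  expect_equal(none$y, 0)
  expect_equal(none$v, 0)

  # interior counts are exact: y * n reproduces the events
  e <- c(1, 7, 13, 29)
  n <- c(8, 20, 40, 30)
  expect_equal(effect_from_counts(e, n)$y * n, e)

  expect_error(effect_from_counts(3, 0), class = "satmeta_domain_error")
  expect_error(effect_from_counts(5, 3), class = "satmeta_domain_error")
})

test_that("CI-mode effects invert the 95% interval width", {
  eff <- effect_from_ci(0.5, 0.4, 0.6)
  expect_equal(eff$y, 0.5)
  expect_equal(sqrt(eff$v), 0.2 / (2 * 1.959964), tolerance = 1e-12)
  expect_equal(sqrt(eff$v), 0.051021, tolerance = 1e-5)

  # round trip: y +/- z * se reproduces the stated interval
  est <- c(0.31, 0.62, 0.05)
  lo <- c(0.21, 0.50, 0.01)
  hi <- c(0.44, 0.71, 0.12)
  # symmetrise so the round trip is exact
  half <- (hi - lo) / 2
  eff <- effect_from_ci(est, est - half, est + half)
  expect_equal(eff$y - 1.959964 * sqrt(eff$v), est - half, tolerance = 1e-9)
  expect_equal(eff$y + 1.959964 * sqrt(eff$v), est + half, tolerance = 1e-9)

  expect_error(effect_from_ci(0.5, 0.6, 0.4),
               class = "satmeta_validation_error")
})

test_that("zero-width intervals are flagged non-poolable", {
  eff <- effect_from_ci(0.3, 0.3, 0.3)
  expect_equal(eff$v, 0)
  ev <- dplyr::bind_rows(
    ci_row("R01", "s1", "SAT", 0.3, 0.3, 0.3),
    counts_row("R01", "s2", "SAC", 5, 10)
  )
  withcols <- study_effects(ev)
  expect_false(withcols$poolable[1])
  expect_true(withcols$poolable[2])
})

test_that("primary outcome selection takes the largest study count, ties lexicographic", {
  df <- tibble::tibble(outcome = c(rep("B", 5), rep("A", 3)))
  expect_equal(select_primary_outcome(df), "B")
  tie <- tibble::tibble(outcome = c(rep("B", 4), rep("A", 4)))
  expect_equal(select_primary_outcome(tie), "A")
  expect_error(select_primary_outcome(tibble::tibble(outcome = character())),
               class = "satmeta_domain_error")
})
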