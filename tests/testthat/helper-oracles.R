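# Independent oracles and fixture builders shared across the suite.

# Literal transcription of the DerSimonian-Laird formulas, kept separate
# from the package's pooling path so the two can be compared.
dl_oracle <- function(y, v) {
  k <- length(y)
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / C)
  ws <- 1 / (v + tau2)
  mu <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  i2 <- if (k < 2) NA_real_ else if (Q == 0) 0 else max(0, (Q - (k - 1)) / Q) * 100
  list(pooled = mu, se = se, Q = Q, tau2 = tau2, i2 = i2)
}

# Exact two-sided signed-rank p by brute enumeration of all 2^n sign
# assignments over the given absolute ranks (average ranks allowed).
signed_rank_enum_p <- function(w_obs, ranks) {
  n <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus <- as.vector(signs %*% ranks)
  p <- mean(w_plus <= w_obs + 1e-9)
  min(1, 2 * p)
}

# Exact two-sided Mann-Whitney p by brute enumeration of all
# choose(n1+n2, n1) assignments of untied ranks to the first sample.
# The folded min-U statistic covers both tails, so no doubling.
mw_enum_p <- function(u_obs, n1, n2) {
  N <- n1 + n2
  subsets <- utils::combn(N, n1)
  u_all <- colSums(subsets) - n1 * (n1 + 1) / 2
  u_all <- pmin(u_all, n1 * n2 - u_all)
  min(1, mean(u_all <= u_obs + 1e-9))
}

# Full exact distribution of min-U over all assignments (for support checks)
mw_enum_dist <- function(n1, n2) {
  N <- n1 + n2
  subsets <- utils::combn(N, n1)
  colSums(subsets) - n1 * (n1 + 1) / 2
}

# Build an untied rank subset of {1..n1+n2} of size n1 with rank-sum
# statistic U exactly u (greedy raise from {1..n1}).
mw_sample_with_u <- function(u, n1, n2) {
  a <- seq_len(n1)
  left <- u
  for (j in rev(seq_len(n1))) {
    gain <- min(left, n2)
    a[j] <- a[j] + gain
    left <- left - gain
    if (left == 0) break
  }
  stopifnot(left == 0, anyDuplicated(a) == 0)
  list(a = a, b = setdiff(seq_len(n1 + n2), a))
}

# evidence-base row builders -------------------------------------------------

counts_row <- function(review, study, design, events, n,
                       flag = FALSE, outcome = "response") {
  tibble::tibble(
    review_id = review, study_id = study, design = design,
    events = as.integer(events), n = as.integer(n),
    estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    clin_het_flag = flag, outcome = outcome
  )
}

ci_row <- function(review, study, design, estimate, ci_low, ci_high,
                   flag = FALSE, outcome = "response") {
  tibble::tibble(
    review_id = review, study_id = study, design = design,
    events = NA_integer_, n = NA_integer_,
    estimate = estimate, ci_low = ci_low, ci_high = ci_high,
    clin_het_flag = flag, outcome = outcome
  )
}

# one review, 2 SAT counts rows + 1 SAC CI row
tiny_evidence <- function() {
  dplyr::bind_rows(
    counts_row("R01", "s1", "SAT", 5, 10),
    counts_row("R01", "s2", "SAT", 12, 30),
    ci_row("R01", "s3", "SAC", 0.5, 0.4, 0.6)
  )
}

# paired differences whose min rank sum is exactly 10 with 7 untied pairs
pairs_w10_n7 <- function() {
  d <- c(1, 2, 3, 4, -5, -6, -7)
  list(x = d, y = rep(0, 7))
}
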