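---
title: "Comparing single-arm trials with single-arm cohorts across systematic reviews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing single-arm trials with single-arm cohorts across systematic reviews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(satmeta)
library(dplyr)
```

## The question

Interventional single-arm trials (SATs) are increasingly accepted as
efficacy evidence, yet there is no agreement on where they sit relative
to their observational counterpart, the single-arm cohort study (SAC):
retrospective chart reviews, registry cohorts and similar designs.
A meta-epidemiological way to probe this is to find systematic reviews
that pooled *both* kinds of single-arm study for the same intervention
and outcome, and ask two questions within each review:

1. Do the two designs give systematically different pooled event
   proportions?
2. Do they differ in how *inconsistent* their studies are, i.e. in
   between-study heterogeneity?

`satmeta` implements that pipeline end to end, plus a synthetic
evidence-base generator with recorded ground truth, so every stage can
be exercised and calibrated without access to any particular set of
extracted review data.

## The model

**Per-study effects.** Each primary study contributes an event
proportion. With raw counts, `y = e/n` and `v = y(1-y)/n`. Some source
reviews only publish an estimate with a 95% CI; since those intervals
are constructed on the natural (untransformed) scale, the standard
error is recovered as `se = (ci_high - ci_low)/(2 * 1.959964)`. All
pooling therefore stays on the raw proportion scale — a logit or
arcsine transform would be statistically more comfortable, but the
downstream estimand is a *risk difference of pooled proportions*, and
CI-mode inputs carry no transformed-scale information to use. Studies
with zero or all events would get zero variance, hence infinite
inverse-variance weight; by default they are nudged to
`y = (e + 0.5)/(n + 1)`, `v = y(1-y)/(n+1)`. The policy is explicit
(`correction` argument) and each corrected study is marked in the
output.

**Within-review pooling.** SAT and SAC subgroups are pooled separately
by DerSimonian–Laird (DL) random-effects meta-analysis: with weights
$w_i = 1/v_i$, Cochran's $Q = \sum_i w_i (y_i - \bar y_{FE})^2$, the
moment estimator is

$$\hat\tau^2 = \max\!\left(0,\; \frac{Q - (k-1)}{\sum w_i - \sum w_i^2/\sum w_i}\right),$$

and the pooled proportion re-weights by $1/(v_i + \hat\tau^2)$.
Confidence intervals are Wald-type with $z = 1.959964$ throughout; no
Knapp–Hartung adjustment is applied, matching the desktop
meta-analysis tooling this pipeline mirrors. Heterogeneity is
summarised by $I^2 = \max(0, (Q - df)/Q)\cdot 100$, with $I^2 \ge 50\%$
classed as substantial (closed bound). For a one-study group $I^2$ is
reported as *undefined* (`NA`), not 0: a single study carries no
information about inconsistency. Such groups are excluded from
heterogeneity comparisons but still pooled.

**Between designs, within review.** The design contrast is the risk
difference $d = \hat p_{SAT} - \hat p_{SAC}$ with
$se_d = \sqrt{se_{SAT}^2 + se_{SAC}^2}$. "Significantly higher/lower"
is operationalised as the two-sided z-test on $d$ at $\alpha = 0.05$
(equivalently, the 95% CI of $d$ excluding zero) rather than visual
overlap of the two subgroup CIs: overlap checking is conservative and
ill-defined as a decision rule. Exact zeros land in a third `tied`
bucket so degenerate inputs stay deterministic.

**Across reviews.** The review-level $(d_j, se_{d_j})$ pairs are pooled
by generic inverse-variance random-effects meta-analysis, again with
the DL estimator — the within- and across-review stages then share one
kernel, and nothing in the across-review stage suggests a different
$\tau^2$ estimator. Directions and significance classes are tallied
alongside.

**Heterogeneity comparison.** Per design, the defined $I^2$ values are
summarised by median and range, and compared twice: the Wilcoxon
signed-rank test on reviews where *both* designs have a defined $I^2$,
and — because paired data are scarce — the Mann–Whitney test on the two
unpaired samples. The conventions are deliberately old-school, chosen
so the arithmetic is reproducible against desktop statistics tools:

* Signed-rank: zeros dropped, average ranks for ties,
  $W = \min(W^+, W^-)$, and the large-sample deviate
  $Z = (W - n(n+1)/4)/\sqrt{n(n+1)(2n+1)/24}$ with *no* continuity and
  *no* tie correction. (With 7 pairs and $W = 10$ this gives
  $Z = -4/\sqrt{35} = -0.6761$; under other conventions that pair of
  numbers is impossible, which is what pins the convention down.) A
  tie-corrected variance is available behind `tie_correction = TRUE`.
* Mann–Whitney: $U = \min(U_a, U_b)$; for untied samples with
  $n_1 n_2 \le 400$ the two-sided p is exact (the folded min-U null
  distribution covers both tails, so the tail probability is *not*
  doubled twice); otherwise a normal approximation with tie-corrected
  variance and a 0.5 continuity correction, where the correction is
  capped so it cannot carry $U$ past the null mean — an uncapped
  correction deflates p-values near 1 by more than the discreteness it
  compensates for.
* Exact small-sample distributions: untied cases use the classical
  signed-rank and rank-sum null distributions; the tied signed-rank
  case enumerates the $2^n$ sign assignments by integer-weight
  convolution (average ranks are half-integers, so doubling makes them
  exact integer weights). Exact mode is the default up to $n = 25$
  pairs.

**Sensitivity analysis.** Studies flagged as clinically heterogeneous
(an *input* — in real use the flags come from blinded reviewer
consensus, which is human judgement outside this package; in synthetic
use they are the generator's ground truth) are removed and everything
is re-run. Reviews whose SAT or SAC subgroup empties drop out of the
paired comparisons with a recorded reason, but their surviving
single-design groups still feed the unpaired Mann–Whitney samples —
the paired and unpaired tests deliberately see different data after
reduction. Per review and design the $I^2$ before/after pairs are
reported, with groups reduced to one study carrying an undefined-after
marker.

## The synthetic evidence base

`simulate_evidence()` draws from the generative model the analysis
implicitly assumes:

* Review baselines $p_j \sim U(0.2, 0.7)$ — the span of objective
  response/remission-type proportions typical of the oncology-heavy
  review samples this pipeline targets.
* Study true log-odds: $\mathrm{logit}(p_j) + \delta_d + \varepsilon$,
  $\varepsilon \sim N(0, \tau_{logit}^2)$ with $\tau_{logit} = 0.3$ by
  default — moderate real-world heterogeneity, enough to put typical
  group $I^2$ values in the 40–80% band actually observed in such
  reviews.
* The design effect `delta_rd` is defined on the estimand's scale: the
  true SAT-minus-SAC risk difference at the review baseline. The SAC
  arm is shifted on the log-odds scale by
  $\mathrm{logit}(p_j - \delta_{rd}) - \mathrm{logit}(p_j)$, which keeps
  every proportion inside $(0,1)$ without clamping (a raw-scale shift
  would need ad-hoc truncation near the boundaries).
* Subgroup sizes default to the `"table1"` preset: the thirteen
  (k_SAT, k_SAC) pairs — from (2, 1) up to (33, 16) — of the review
  sample the pipeline was built around, including its one-study
  subgroups, so simulations inherit the real data shape. Per-study
  sample sizes are uniform on 20–200, the typical single-arm study
  range.
* A fraction of studies (`outlier_fraction`, default 0) receives an
  extra log-odds shift (default 1.0, roughly +20 percentage points at a
  0.5 baseline) and is flagged, emulating clinically heterogeneous
  outliers with a recoverable ground truth.

One seed drives all draws; `run_recovery()` derives replicate seeds as
`seed + r` so studies are reproducible end to end.

What the generator does *not* emulate — and what green tests therefore
do not certify about real data — includes: selection and measurement
bias mechanisms (assessor non-independence, attrition), correlation
between a study's size and its true effect, design misclassification by
review authors, and CI-mode rounding in source publications (the
generator emits counts-mode records only, though the analysis accepts
both).

## Numerical choices and degenerate inputs

* $z_{0.975}$ fixed at 1.959964 everywhere, so CI arithmetic round-trips
  bit-stably.
* $\tau^2$ and $I^2$ truncate at zero; $Q \le df$ collapses DL to the
  fixed-effect answer exactly.
* A zero-width CI yields $v = 0$: tolerated alone in a subgroup
  (`k = 1`, zero-width pooled CI) but refused with a clear error when
  it would have to share a pool with other studies.
* Outcome-label ties in `select_primary_outcome()` break
  lexicographically; direction ties get their own bucket.
* All-flagged evidence degrades to a warning plus an empty reduced
  side, never an error, so batch sensitivity runs survive extreme
  replicates.

## Worked example

```{r example}
sim <- simulate_evidence(sim_config(delta_rd = -0.07,
                                    outlier_fraction = 0.15,
                                    seed = 42))
sens <- run_sensitivity(sim$evidence)
glance(sens$main)
sens$dropped
```

The forest of within-review risk differences and the before/after
heterogeneity scatter come straight off the result objects:

```{r plots, eval = FALSE}
autoplot(sens$main$comparisons)
plot_pooled_proportions(sens$main$comparisons)
autoplot(sens)
```

## Calibration and recovery

`run_recovery()` wraps the simulate–analyse loop. The package's own
checks run it at three operating points (sizes chosen to give stable
Monte-Carlo estimates on a single core):

* **Null calibration** — `delta_rd = 0`, preset shapes, 1,000
  replicates: the two-sided test on the pooled risk difference rejects
  at close to, and slightly above, the nominal 5% (DL with 13 reviews
  and a normal reference is mildly anti-conservative; the acceptance
  band used is 2–9%).
* **Recovery** — `delta_rd = -0.07`, 500 replicates: the mean pooled
  risk difference lands within ±0.015 of the truth and 95% CI coverage
  in the 0.90–0.97 band. A small attenuation toward zero is expected:
  the design effect is exact at the review baseline but the logit-scale
  noise makes each study's expected proportion shrink slightly toward
  0.5.
* **Sensitivity behaviour** — 15% flagged outliers, 200 replicates: in
  at least 70% of replicates removing the flagged studies does not
  increase the median within-group $I^2$. It is not near 100%: removing
  a handful of studies from small groups adds sampling noise to
  $I^2$, and reviews dropping out shift the median's support.

## Limitations

* Raw-proportion-scale pooling is faithful to the design but inherits
  its known defects: variance depends on the mean, and CIs near 0 or 1
  are not range-respecting.
* The within-review significance rule (z-test on $d$) is one of
  several defensible choices; results near the boundary can differ
  under CI-overlap-style rules.
* The across-review pool treats review-level risk differences as
  exchangeable; with a handful of reviews, $\hat\tau^2$ is noisy and
  the Wald test's mild anti-conservatism is visible in the calibration
  numbers above.
* Exact rank tests are exact only for untied data; I² samples are
  continuous in practice, but heavily truncated samples (many zeros)
  will route through approximations.
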