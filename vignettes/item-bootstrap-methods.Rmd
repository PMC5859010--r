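---
title: "Assessing reliable individual change by bootstrapping item responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing reliable individual change by bootstrapping item responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itemboot)
```

## The problem

A person answers the same J-item scale twice, before and after an
intervention (or answers two parallel forms once). Did their score
really change, or is the observed difference within what measurement
error alone would produce? Classical answers to this question require
the test's psychometric properties — population mean, variance,
reliability — and fail when those are unknown, estimated on a different
population, or simply not trustworthy.

`itemboot` frames the decision through per-occasion confidence
intervals: a change is *reliable* (statistically significant) when the
pre- and post-occasion intervals do not overlap. Two interval
constructions are provided, one classical and one that needs no test
properties at all.

## The item bootstrap (BSI)

The individual's own J item responses form an empirical distribution.
If the items map the construct adequately, those J values carry the
essential information about how this person responds to items of this
kind. The BSI procedure:

1. treat the J responses as the empirical response distribution;
2. draw J values from it with replacement and sum them into a total
   score; repeat B times (default `B = 3000`);
3. take the B scores as the sampling distribution of this person's total
   score and read confidence bounds off its percentiles — 2.5th and
   97.5th for a two-sided 95% interval.

No distributional assumptions enter. Two structural consequences are
worth noting, because they are tested as invariants:

* **Bound property.** A resampled score is a sum of J observed
  responses, so it can never leave `[J·min(x), J·max(x)]`, a subset of
  the possible score range. Classical intervals can and do leave that
  range; the package deliberately does not clip them (see below).
* **Adaptive width.** Two respondents with the same total score but
  different response spread get different intervals: heterogeneous
  responses mean more uncertainty and a wider interval. Classical
  intervals have the same width for everyone.

The limiting case is a respondent who answers every item identically:
the bootstrap distribution is a constant and no interval exists. `bsi()`
raises a typed error for such *degenerate* vectors; pipeline functions
record the respondent as `indeterminate` and exclude them from rate
denominators for *all* methods, so methods are always compared on the
same people.

### BCa adjustment

The default interval applies Efron and Tibshirani's bias-corrected and
accelerated (BCa) adjustment to the percentile levels before reading the
bounds:

* bias correction `z0 = qnorm(#{θ* < θ̂} / B)`. Resampled integer scores
  tie with the observed score often; the count is *strictly below*,
  following the standard BCa formulation (a tie-heavy unit test pins
  this down). If no resampled score falls on one side of the observed
  score, `z0` is infinite and the function falls back to the plain
  percentile interval with a warning.
* acceleration `a` from a jackknife. BCa needs jackknife replicates of
  the statistic; for a total score the natural reduction is through the
  item mean. We leave out one item at a time and rescale the remaining
  sum back to the J-item score scale, `θ₍ᵢ₎ = J/(J−1) · (X − xᵢ)`, so
  that replicates live on the same scale as the statistic. The
  acceleration is the usual standardised jackknife skewness; it is
  invariant to the rescaling, which is kept only for interpretability.
  Zero jackknife variance sets `a = 0` with a warning.
* adjusted levels `α_k = Φ(z0 + (z0 + z_k)/(1 − a(z0 + z_k)))`, read off
  the bootstrap distribution by empirical quantile.

All empirical quantiles use linear interpolation between order
statistics (R's type 7). The convention matters little at `B = 3000`
(differences are sub-unit on integer score scales) but is fixed and
documented so results are exactly reproducible.

## The classical comparator (ETS)

The estimating-the-true-score interval shrinks the observed score toward
the group mean by the reliability and adds a constant-width band:

$$V'_i = \hat\rho_{xx'} X_i + (1-\hat\rho_{xx'})\hat\mu_x, \qquad
  \hat\sigma_e = \hat\sigma_x\sqrt{1-\hat\rho_{xx'}}, \qquad
  V'_i \pm z\,\hat\sigma_e .$$

Cronbach's alpha estimates ρ̂ₓₓ′; all variances use the n−1 denominator
consistently (the convention cancels in alpha only if used consistently
in numerator and denominator). Numerical choices:

* **z values.** By default exact normal quantiles (1.959964…,
  1.644854…). `paper_rounding = TRUE` uses the conventional printed
  1.96 / 1.64 so that textbook arithmetic reproduces bit-for-bit.
* **Negative alpha** is mathematically possible and is reported, but the
  SEM is computed with alpha clamped to 0 (otherwise the SEM would
  exceed the score SD, which the classical model does not contemplate);
  a warning and a flag record the clamp.
* **No clipping.** ETS limits may fall outside the possible score range;
  that is a known weakness of classical intervals and is left observable
  on purpose — the report flags out-of-range limits instead of hiding
  them. Keeping the flaw visible is what makes the ETS/BSI contrast
  meaningful.
* **Which sample supplies μ̂ₓ, σ̂ₓ, alpha?** Nothing forces the pre and
  post administrations to share statistics. The default (`stats_source =
  "each"`) estimates them per administration — each occasion's interval
  is built from that occasion's measurement properties; `"pre"` and
  `"pooled"` are available for sensitivity analysis.

## The decision rule

`detect_change()` declares significance when intervals are disjoint,
with **strict** inequalities: the rule is "the lower limit of one
exceeds the upper limit of the other", so intervals sharing a bound
overlap and the verdict is no-change. Exact ties are flagged in the
report. When the intervention's direction is known, one-sided intervals
are used (z = 1.64 for ETS; the 95th percentile of the pre distribution
against the 5th of the post, or vice versa, for BSI) and only the
expected ordering counts. By default the BCa adjustment is applied to
one-sided levels as well; `one_sided_percentile = TRUE` forces raw
percentiles for the one-sided bounds.

## Parallel forms from one administration

With a single administration, false-positive behaviour can still be
studied by splitting the test into two half-tests treated as parallel
forms administered simultaneously — between which no individual can have
truly changed. After recoding inverse items, the items are ordered by
sample mean and dealt into halves in the repeating pattern A,B,B,A
(first and fourth of each quartet to half 1, second and third to half
2), which keeps half-test totals as similar as possible. Ties in the
ordering break by original index — the split (and hence downstream
rates) depends on this, so it is fixed and stable. Odd item counts
continue the pattern, leaving halves that differ by one item (flagged;
half scores are not rescaled).

Equivalence is then verified: a paired t-test on the half-score
differences for the means, and the Pitman–Morgan test (t-test of the
correlation between half-score sums and differences) for the variances
— chosen as the standard parametric test for correlated variances.
Identical halves (all differences zero) make the tests inapplicable and
count as equivalent; a constant nonzero offset is a sure mean difference
(`p = 0`).

## The simulator

The simulation harness is the package's test bed, not a model of any
particular instrument. Respondent i has a latent trait θᵢ ~
Normal(`true_score_mean`, `true_score_sd`) on the item response scale;
the response to item j is `round(θᵢ + e)` with `e ~ Normal(0,
item_noise_sd)`, clipped to the response bounds; administrations are
conditionally independent given θ, and an intervention shifts θ by
`change_delta` latent units. This is the simplest mechanism producing
bounded ordinal responses with controllable heterogeneity, and its
moments have a closed form (normal quadrature over rounding cells)
against which the generator is tested.

Defaults describe a 24-item five-point half-test answered by a
moderately homogeneous sample: θ ~ Normal(3, 0.6), item noise SD 0.8,
1000 respondents, B = 1000, 95% level. Under these defaults roughly no
respondents are degenerate; pushing θ toward a scale end or shrinking
the noise produces ceiling effects and degenerate respondents, which is
itself a tested path.

What the simulator does *not* emulate: item-specific difficulties or
loadings (items are exchangeable), ordinal thresholds beyond uniform
rounding, missing data, practice or regression-to-the-mean effects, and
test-retest correlation beyond the shared latent trait. Passing
calibration tests on this generator therefore shows the procedures
behave correctly under a clean classical-test-theory-like regime; it
does not certify behaviour on any particular real instrument.

`run_null_study()` (two administrations from the same θ, two-sided
detection) measures false-positive rates: under the strict non-overlap
rule both ETS and BSI stay *below* the nominal 5% — the rule is
conservative by construction. `run_change_study()` (shifted θ, one-sided
detection in the direction of the shift) measures power, which rises
monotonically with the shift and with J until ceiling effects bite.
Rates are computed across respondents within a replication and averaged
over replications; the Monte-Carlo standard error comes from the
replication-level variance, or from the binomial formula for a single
replication.

## Problem sizes and runtime choices

The test suite runs the null calibration at 1000 respondents × 24 items
with B = 1000 (a few seconds), the power grid at the same size over
latent shifts {0, 0.25, 0.5, 1}, exact-enumeration checks of the
bootstrap percentiles at J ∈ {3, 4} (where all J^J resamples are
enumerable), and property checks (bound preservation, involution,
reproducibility) over hundreds of randomized cases with fixed seeds.
Unit-level oracles include a hand-computed covariance-matrix alpha, the
printed classical-interval arithmetic, and BCa bounds cross-checked once
against an independent implementation on a frozen distribution.

## Known limitations

* BSI intervals for very homogeneous responders are narrow and can be
  anti-conservative in the extreme; fully constant responders are
  excluded outright. How much item-level variability BSI needs to
  perform well is an open research question.
* B = 3000 makes seed-to-seed interval variation sub-unit on typical
  score scales but not zero; seeds are therefore mandatory in the API
  and logged in every report.
* The non-overlap rule is conservative: its false-positive rate sits
  below the nominal alpha rather than at it. Raising the nominal level
  is a legitimate knob (`level`), and the harness exposes it.
* Percentages in rate summaries are rounded half-up to one decimal for
  table formatting; computations always use the unrounded values.
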