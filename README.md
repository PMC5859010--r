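# itemboot

Deciding whether one person's score really changed between two
administrations of a questionnaire usually requires the test's
psychometric properties — its population mean, variance and reliability.
When a test is still in development, only a subset of its items was
applied, or the known norms do not transfer to the population at hand,
those properties are unknown or untrustworthy and the classical reliable
change methods cannot be used.

`itemboot` implements the **item bootstrap (BSI)**: resample, with
replacement, the J item responses an individual gave at one occasion,
sum each resample into a total score, and repeat B times (default
B = 3000). The resulting distribution stands in for the unknown
distribution of scores that person would produce over repeated
administrations, and a confidence interval is read off its percentiles —
plain, or adjusted with Efron and Tibshirani's bias-corrected and
accelerated (BCa) method. A **reliable change** is declared when the pre-
and post-occasion intervals do not overlap (strictly: the lower limit of
one exceeds the upper limit of the other).

For comparison the package also implements the classical **ETS**
(estimating-the-true-score) interval,

V′ᵢ = ρ̂ₓₓ′·Xᵢ + (1 − ρ̂ₓₓ′)·μ̂ₓ,  σ̂ₑ = σ̂ₓ·√(1 − ρ̂ₓₓ′),  95% CI: V′ᵢ ± 1.96·σ̂ₑ,

with Cronbach's alpha as the reliability estimate ρ̂ₓₓ′. Unlike the ETS
interval, the BSI interval can never leave the range of possible scores,
and its width adapts to how heterogeneous the individual's responses are.

The package also provides:

* **ABBA split-half construction** of two parallel forms from a single
  administration (items ordered by sample mean, assigned A,B,B,A,...),
  with paired mean and Pitman–Morgan variance equivalence tests — the
  setting in which every detected "change" is a false positive;
* **one-sided directional rules** (z = 1.64; 5th/95th percentiles) for
  interventions with a known expected direction;
* a **simulation harness** (latent trait + discretised clipped normal
  item noise) measuring false-positive calibration and power of both
  methods;
* CSV in, TSV/JSON reports out, and a thin command-line interface
  (`inst/cli/itemboot.R`) with `detect`, `split`, `simulate` and
  `describe` subcommands.

## Worked example

An 8-item Likert 1–5 self-efficacy-style questionnaire applied before
and after an intervention expected to raise scores:

```r
library(itemboot)
sp <- scale_spec(n_items = 8, scale_min = 1, scale_max = 5,
                 direction = "increase")

cfg <- sim_config(n_respondents = 110, n_items = 8)
set.seed(42)
theta <- rnorm(110, 2.6, 0.6)                      # latent trait
pre  <- generate_administration(theta,       cfg, seed = 1)
post <- generate_administration(theta + 0.6, cfg, seed = 2)

fit <- reliable_change(pre, post, sp, method = "both",
                       level = 0.95, B = 3000, seed = 99)
fit
#> Reliable change analysis: 110 respondents, 8 items, 95% level, direction: increase
#> ETS (N = 109, 1 indeterminate excluded): 14 (12.8)
#> BSI_bca (N = 109, 1 indeterminate excluded): 28 (25.7)
#> Note: 7 exact tie(s) at compared bounds (count as overlap)
```

Both methods report, in "n (percent)" form, how many of the evaluable
respondents show non-overlapping one-sided 95% intervals — i.e. a
reliable increase. One respondent answered every item identically at
some occasion; their bootstrap distribution is a constant, so they are
excluded from both denominators (`indeterminate`). Per-respondent
intervals are available directly:

```r
bsi_interval(pre[1, ], level = 0.95, B = 3000, seed = 7, spec = sp)
#> BSI_bca 95% two_sided CI: [21.00, 27.00] (center 25.00)
ets_interval(sum(pre[1, ]), estimate_reliability(pre), spec = sp)
#> ETS 95% two_sided CI: [19.68, 28.70] (center 24.19)
```

`fit$respondents` holds the full per-respondent table (scores, every
interval bound, verdicts, degeneracy / out-of-range / tie flags);
`run_detect()` and `run_split()` wrap the same analysis around CSV files
and written reports.

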