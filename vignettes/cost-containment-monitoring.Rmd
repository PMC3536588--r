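---
title: "Monitoring cost containment with XmR charts and the intraclass correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring cost containment with XmR charts and the intraclass correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmricc)
```

## The model in two stages

`xmricc` turns a wide panel of monthly reimbursement totals (providers in
rows, consecutive calendar months in columns) into a yearly homogeneity
index and a monthly outlier triage, in two stages.

**Stage 1 — XmR scoring.** Each provider is treated as its own process.
For month $t$, the trailing window of the previous 12 months (the scored
point excluded) supplies the central line $CL_t$ (window mean) and the
process sigma via the individuals-chart estimator
$\hat\sigma_t = \overline{mR}/1.128$, where $\overline{mR}$ is the mean
absolute successive difference *within the window* and 1.128 is the $d_2$
bias constant for subgroups of size 2. The score is the signed distance
$(x_t - CL_t)/\hat\sigma_t$. The first 12 months are burn-in and yield no
scores. Because the baseline moves with the provider, the score is
invariant under any positive affine rescaling of that provider's series —
currency units, inflation indexing, and hospital size all cancel, which
is what makes scores comparable across providers of very different
volume.

**Stage 2 — ICC per calendar year.** The scored months of one year form a
complete $n \times 12$ grid of band codes. A two-way ANOVA without
replication decomposes it into provider, month, and residual sums of
squares, and the homogeneity index is the two-way consistency-type
*average-measure* intraclass correlation
$\mathrm{ICC}(C,k) = (MS_{rows} - MS_{err})/MS_{rows}$, numerically equal
to Cronbach's $\alpha$ of the 12 months treated as parallel raters of the
providers. Removing the month main effect is deliberate: a calendar-wide
payment-policy shift moves every provider and should not count as
heterogeneity. An ICC near (or below) zero says the months cannot tell
providers apart — collective containment; a high ICC says some providers
persistently sit in different bands than others.

The 95% interval is the F-based (Feldt-type) one built on
$F = MS_{rows}/MS_{err}$ with $(n-1)$ and $(n-1)(k-1)$ degrees of
freedom. This specific flavor — two-way, consistency, average measures,
F-pivot interval — is pinned by tests that must reproduce two published
interval pairs at $n = 421, k = 13$ to within ±0.005; single-measure and
absolute-agreement variants do not reproduce them.

Derived indices: $\mathrm{SEM} = SD_x\sqrt{1-r}$ (here a *large* SEM
relative to the spread means homogeneity, i.e. good collective control),
the separation index $G_p = \sqrt{r/(1-r)}$, and
$\mathrm{strata} = (4G_p+1)/3$, the number of statistically resolvable
performance levels; ICC below 0.5 gives strata below 1.67 — effectively
one stratum. The yearly trend is summarized by the Pearson correlation of
ICC against year, with $t = |r|\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df.

## Tunable parameters

* `baseline_length` (months, default **12**): the trailing window. One
  full year makes the baseline seasonally balanced; shorter windows react
  faster but estimate sigma poorly (at least 2 is enforced, but below ~8
  the moving-range estimate is very noisy).
* `scheme` (default **`"ten_band"`**): how distances become ordinal
  codes. `ten_band` mirrors the chart's cumulative band labels:
  $\mathrm{sign}(sd)\cdot\min(4,\lceil|sd|\rceil)$, signed codes
  $-4..-1, +1..+4$. `five_band` (round, clip to $\pm 2$, shift to $0..4$)
  produces the 5-category 0-based scale used for rating-scale
  comparisons. Both are first-class; the yearly ANOVA runs on whichever
  the scan produced (or on the continuous SD layer via `use = "sd"`).
* `zero_band` (default **+1**): a distance of exactly 0 belongs to
  neither the below- nor the above-CL band, so a tie rule is required; it
  is configurable because the choice is genuinely arbitrary. It matters
  only for constant series, where all scores are exactly 0.
* `threshold` (SD units, default **2**) for the bubble flags: `outlier`
  requires *both* the current and previous month strictly beyond the
  threshold with the same sign (a sustained deviation); one exceedance,
  or two with mixed signs, is `watch`. Boundary equality does not flag.
  Flag counts are monotone non-increasing in the threshold.
* `alpha` (default **0.05**): two-sided error rate of the ICC interval;
  p-values are reported and compared to 0.05 for the `significant` flag,
  nothing else is automated on them.

## Numerical choices and degenerate inputs

* **Zero sigma** (a constant baseline window) does not abort the scan: the
  score is 0 on the central line and otherwise $\pm 4$ (the band cap).
  Monitoring must not fall over on a provider that bills identically
  every month.
* A **constant year block** has no F statistic; the ANOVA and ICC carry a
  `degenerate` flag and `NA` rather than a fabricated value. `MS_err = 0`
  with row variance present gives ICC exactly 1.
* Negative ICCs are reported as computed, never truncated at zero — the
  null sampling distribution extends below zero and truncation would bias
  the yearly trend.
* `ss_error` is obtained by subtraction and clamped at 0 against
  floating-point cancellation; additivity is property-tested at 1e-9.
* Five-band rounding uses R's `round` (round-half-even); the half-integer
  boundary cases are measure-zero for continuous scores.
* A constant yearly ICC sequence has no defined trend correlation; the
  result is flagged, not forced.

## What the simulators emulate

`generate_expenditure_series()` builds demo panels: each provider gets a
lognormal base level (median 1000 currency units, sdlog 0.5 — a
right-skewed size distribution typical of provider panels), an optional
multiplicative monthly drift, and additive Gaussian noise with SD equal
to `noise_cv` × base (default 0.05). Injected shocks add
`size × base × noise_cv` to chosen cells; because the XmR sigma of an iid
normal series estimates the noise SD itself, `size` is approximately the
SD distance the shock scores, which gives outlier-recovery tests a known
ground truth. Shocks of 5 units over two consecutive months are recovered
as `outlier` at threshold 2 in every seeded test replicate.

What it does *not* emulate about real claims data: serial correlation in
demand, seasonality, policy breaks, provider entry/exit, heavy-tailed
month-to-month jumps. Passing tests on these panels validates the
*mechanics* (scoring, alignment, flag logic), not the field behavior of
the method.

`scenario_spec()` / `generate_scenario_matrix()` build Rasch rating-scale
matrices for calibration. Cells are drawn from
$P(X=j) \propto \exp\!\sum_{l\le j}(\theta - \delta - \tau_l)$ with 5
categories. The scenarios encode: dispersed persons
($\theta\sim N(0,1)$) with item difficulty drifting 2.0→−1.0
(*increasing*), −2.0→1.0 (*decreasing*), flat 0 (*out_of_control*), and
identical persons $\theta=0$, $\delta=0$ (*in_control*);
`combine_scenarios()` stacks two populations 50/50 (the odd row goes to
the first). Over repeated seeds, dispersed-person scenarios produce
systematically higher ICCs than the identical-person one, and a mixture
lands between its components — the qualitative ordering the calibration
is for.

Design choices the rating-scale setup required:

* **Thresholds** default to equally spaced, centered
  $(-1.5, -0.5, 0.5, 1.5)$. Scenario ICCs are threshold-sensitive, so the
  vector is an explicit argument rather than a constant.
* **Difficulty endpoints are interpolated linearly** across the items;
  only the endpoints of the drift are specified by the scenarios.
* **Two generation pipelines** exist because the scenario design admits
  two readings: `direct` (default) analyzes the sampled categories
  themselves, `xmr` treats the categories as a monthly series, runs the
  sequential scan, and analyzes the resulting five-band codes. Neither is
  privileged; the in-control scenario in particular yields a near-zero
  ICC under `direct` generation (identical persons are exchangeable by
  construction), so quantitative in-control reference values depend on
  the pipeline and are treated as exploratory, not as calibration
  constants.
* **Reproducibility contract**: every generator is a pure function of
  (spec, seed); each row draws from a substream derived from the seed and
  the row index, so enlarging the population never reshuffles the rows
  already generated.

## Problem sizes

The test suite property-checks the engines at small sizes (grids up to
12 × 7, panels up to 421 × 132 once) and runs the null calibration at
421 × 13 over 150 seeds, which keeps the default run near five seconds.
The acceptance script uses 1000 seeds for the null mean, a size at which
the Monte Carlo standard error of the mean ICC is about 0.002.

## Known limitations

* Months are treated as independent raters; XmR scores from overlapping
  trailing windows are in fact weakly serially dependent, which pushes
  null ICCs slightly below zero (visible in the README example). The
  index is therefore best read comparatively across years, not as an
  absolute zero point.
* Ordinal band codes enter the ANOVA as numeric scores; this is the
  method's own convention, and a flag (`use = "sd"`) allows the
  continuous distances instead.
* Whole-row exclusion of providers with any missing month is the only
  missing-data policy; no imputation is offered, so results describe the
  always-reporting cohort.
* The bubble rule looks back exactly one month; longer sustained drifts
  are visible only through repeated monthly flags, not a built-in run
  rule.
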