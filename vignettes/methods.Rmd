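---
title: "Harmonizing weekly death counts and estimating excess mortality: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing weekly death counts and estimating excess mortality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weeklymort)
library(dplyr)
```

## The problem

National statistical offices publish weekly all-cause death counts in
whatever classification their registration system produces: some by 5-year
age groups and sex, others only for broad intervals like 0–64/65+ or for
both sexes combined, occasionally with deaths of unknown age. Comparing
mortality shocks — pandemics, heat waves, severe influenza seasons — across
countries requires a single harmonized layout. `weeklymort` implements the
full processing chain for one country series: raw weekly counts in, a
harmonized table of deaths and person-week death rates in five standard age
groups (0–14, 15–64, 65–74, 75–84, 85+) by sex out, together with weekly
excess-mortality estimates and a machine-readable consistency report.

Nothing is smoothed and nothing is adjusted for undercount. Every
adjustment that *is* made — redistribution of unknown ages, age and sex
splitting, forecast exposures — is proportional, conserves totals, and is
visible in the output through the `Split`, `SplitSex` and `Forecast` flags
or the run log.

## Harmonization: three proportional operators

All three adjustments borrow the *annual* structure of mortality, on the
assumption that the within-year weekly age and sex composition is stable.

**Age splitting.** A weekly count $D_y^w(x, x+b)$ in a broad source
interval $[x, x+b)$ is split into a nested target group $[x, x+a)$
proportionally to the annual death counts of the same year and sex:

$$\hat D_y^w(x, x+a) = D_y^w(x, x+b)\cdot
  \frac{D_y(x, x+a)}{D_y(x, x+b)}.$$

Within each source interval the split counts sum exactly to the source
count, so the operation conserves every stratum total by construction.
Every target group must nest in exactly one source interval; a grouping
like 0–17/18–64 cannot be mapped onto a 0–14/15–64 target and is rejected
with an alignment error rather than approximated. Model-based ungrouping
(splines, penalized composite links) is deliberately out of scope: under a
pandemic age shift those models have no validated behaviour, while the
proportional rule has a transparent, quantifiable bias (measured below).

**Sex splitting.** Both-sex weekly counts are split by the annual sex
ratio of deaths in the same age group,
$\hat D^{w,males}_y = D^{w,total}_y \cdot D^{males}_y / D^{total}_y$,
with the female count taken as the exact remainder so that
male + female reproduces the input cell to the last bit.

**Unknown ages.** Deaths of unknown age are allocated proportionally to
the known-age counts of the same (year, week, sex) stratum. If the
stratum's known counts are all zero the annual age distribution of the same
year and sex is used; if that is also empty the record is unprocessable and
the run stops. This fallback hierarchy is explicit because a silent choice
here would be a silent bias; every fallback use is logged.

The fixed order is unknown-age → age split → sex split. For proportional
operators the first two commute whenever the fallback is not triggered (the
test suite asserts this on random fixtures), so the ordering is a
documentation decision, not a numerical one.

**When is the split exact?** If the weekly age distribution equals the
annual one in every week (week-stationarity), coarsening and re-splitting
reproduces the fine table to machine precision. A shock concentrated at old
ages breaks this: shock-week deaths get spread according to the annual
distribution, understating old-age and overstating young-age mortality in
those weeks. The acceptance suite constructs exactly this case (a doubling
of old-age mortality over seven weeks) and measures the resulting
cell-level bias rather than pretending it away; using broad, few age groups
keeps it small.

## Week calendars and the 52-week year

Weeks follow ISO-8601 by default: Monday start, week 1 contains the year's
first Thursday (equivalently January 4). Known national exceptions are
configurable per country: Sunday start (USA), Saturday start (England &
Wales, Northern Ireland), and a January-1 restart (Australia). For the
Sunday/Saturday schemes no international standard defines week 1; this
package anchors week 1 as the week containing January 4 — the direct
analogue of the ISO rule — and documents that as a convention.

A statistical year always has 52 weeks. Week-53 records (long ISO years;
the 1–2 day remainder of January-1 numbering) are merged into week 52 by
default so that no deaths are lost; a `drop` mode exists for users who
prefer truncation. Every merge is logged. The ISO implementation is ~20
lines of date arithmetic and is tested against the C library's independent
`%G`/`%V` week numbering over all dates 1990–2030.

## Lee-Carter forecasting of missing annual data

Weekly data usually outrun the annual deaths/exposure series by one to four
years. For those years the annual table is extrapolated with a Lee-Carter
model fitted per sex to annual rates $m(x,t)$:

$$\log m(x,t) = a_x + b_x k_t, \qquad \textstyle\sum_x b_x = 1,\;
\sum_t k_t = 0,$$

with $a_x$ the row means of the log rates and $(b_x, k_t)$ the leading
singular pair of the centered log-rate matrix. The period index is forecast
by a random walk with drift, using the standard drift estimator
$(k_T - k_1)/(T-1)$; only the central path is used because the pipeline
needs point exposures (the innovation SD is retained on the fitted object
for users who want intervals). No second-stage re-estimation of $k_t$
against total deaths is applied — the classical "jump-off" adjustment is
omitted for transparency, and the fixed-point property (refitting on rates
regenerated from a fit reproduces the fit) is tested instead.

Numerical choices:

* **Fit window** — default start 2005. A short, recent window keeps the
  drift focused on current mortality change and is comparable across
  countries. `lc_sensitivity()` reports how much the forecast rates move
  across candidate windows; on log-linear synthetic mortality the movement
  is numerically zero, and the function exists precisely so users can
  measure it on their own data instead of trusting a blanket claim.
* **Zero rates** are floored at half a death over the group's exposure
  before logs are taken (or at half the smallest positive rate when no
  exposures are available); every floored cell is recorded on the fit.
* **Exposure projection** under zero migration uses cohort bookkeeping on
  broad groups with a uniform within-group age distribution: the one-year
  slice at each group's upper edge ($E_g / w_g$) survives with probability
  $e^{-m_g}$ into the next group, the remainder survives in place, the open
  group accumulates, and entry into the youngest group is held constant at
  its last observed level. The projected population serves directly as the
  person-years estimate — a deliberate simplification (no mid-year
  averaging), acceptable at horizons of 1–4 years.

Forecast-derived rows carry `source = "forecast"` and every output row of
an affected year gets `Forecast = 1`.

## Weekly rates and excess mortality

The person-week death rate divides the weekly count by one week of annual
exposure, $m_y^w = \hat D_y^w / (E_y/52)$, which makes weekly rates
directly comparable with annual rates: under uniform weekly deaths the mean
weekly rate equals the annual rate exactly.

Excess is the plain difference between observed and expected weekly rates
(counts via rate × exposure/52). The expected schedule comes from a
registry of baseline methods: the conventional week-specific mean over a
reference window (default, e.g. 2015–19), a week-specific median, a
per-week OLS trend evaluated at the target year, the lowest-mortality
reference year, a verbatim specific year, and a trimmed week-mean that
discards extreme reference values. The registry is a documented stand-in
for the range of reference-level definitions in circulation — the point is
that the choice is explicit and switchable, not that these six are
canonical. Incomplete recent weeks (registration lag) are handled by an
explicit completeness-cutoff week; no back-casting is attempted because a
registration date cannot be converted into an occurrence date.

### Design of the shock-recovery experiment

The test and acceptance suites measure the estimator on a simulated
7-week shock of 500 excess deaths against a 5-year week-mean baseline. The
experiment uses a small-country configuration (the default population
scaled to ≈500&nbsp;000) and cumulates excess over the shock window. That
scaling is a signal-to-noise design choice made before running the
experiment: the windowed estimator's sampling SD is roughly
$\sqrt{1.2\,\lambda_{window}}$ (observed Poisson noise plus a fifth of it
again from the 5-year baseline mean), ≈37 deaths at this population size,
so a 2% bias bound on a 500-death shock is actually informative about bias;
at ten million population the same bound would be decided by noise.

## Consistency checks and outlier flags

Validation is report-only and pure: checks never mutate or fix data, and a
pipeline run never aborts on a failing check — it documents it.

* age-group sums vs the all-ages total (every row);
* male + female vs both-sex (every year, week, group);
* processed weekly totals vs raw weekly totals (harmonization must
  redistribute, never create or destroy);
* male/female rate ratios within a plausibility band (warning only);
* yearly sums of weekly deaths vs official annual totals, pass within a
  default 1% (none of these thresholds is canonical; all are config
  arguments).

Outlier flagging centers each week's rate on the same-week median across
the *other* years (leave-one-out) and scores residuals with a robust
z-score whose scale is the MAD of residuals pooled over all weeks. The
pooling is essential: with the typical 5-year history a per-week MAD rests
on 5 values, and a 4-sigma rule on so noisy a scale estimate false-flags
orders of magnitude more null weeks than its nominal level suggests. The
pooled leave-one-out design keeps the Poisson-null false-flag rate below
0.5% of weeks (asserted over 500 simulated replicates in the test suite,
where it lands far below that bound) while still flagging a doubled week
instantly.
Flags are advisory; pandemic weeks are signal, not errors, which is also
why the center and scale are robust statistics.

## The synthetic generator: what it does and does not emulate

`simulate_mortality()` produces internally consistent triples (raw weekly
records, annual table, official totals) with stored ground truth. Expected
weekly counts are annual rate × exposure/52, modulated by a sinusoidal
seasonal factor peaking at week 2 (amplitude configurable, mean exactly 1
over 52 weeks), a log-linear secular trend, and an optional shock —
additive total deaths or a rate multiplier, concentrated at old ages by
default, mirroring the age profile of recent pandemic mortality. Counts
are Poisson draws around these expectations (or the expectations
themselves in noise-free mode). Annual death counts are *defined* as the
sums of the fine weekly truth, so every generated dataset passes the
internal checks by construction, and the coarsen→harmonize round trip is
exact in the noise-free week-stationary case — the right property for
testing, because any deviation is then attributable to the pipeline.

`coarsen()` re-publishes the fine table the way a source country would:
broad age groups, optionally combined sexes, optionally a fraction of each
stratum moved to an unknown-age row. The unknown-age extraction is
deterministic and proportional across ages rather than a random thinning —
this keeps the round-trip identity exact and the truth bookkeeping simple.

What the generator does **not** emulate: registration-week artifacts
(holiday dips, end-of-period spikes), week-to-week serial correlation
beyond the seasonal curve, age-varying seasonality, population change
within a year, multi-region correlation, or reporting-lag truncation.
Passing tests therefore demonstrate the correctness of the *operators*
under the model's assumptions, not the absence of these real-world
complications.

## Problem sizes and reproducibility

The test and acceptance runs use deliberately modest sizes chosen to
exercise every code path with stable statistics: 1000 random strata for
the conservation properties, 100 replicates for the noisy Lee-Carter
recovery (5 ages × 15 years, exposure $10^5$), 200 replicates for the
shock experiment, 500 replicates for the outlier null, and all ~15 000
days of 1990–2030 for the calendar check. All simulations are seeded;
`run_pipeline()` with identical config, inputs and seed is byte-identical,
and `Rscript scripts/acceptance.R --seed N --out f.json` recomputes every
reported quantity from scratch.

## Known limitations

* The proportional age split is biased when a shock shifts the weekly age
  distribution; the bias is measured, not corrected.
* The Lee-Carter forecast is a central path; exposure uncertainty is not
  propagated into rates or excess.
* The cohort projection's uniform within-group age assumption is crude for
  the 15–64 group; at horizons ≤4 years the induced error is small
  relative to the drift uncertainty.
* Week-1 anchoring for Sunday/Saturday schemes is a package convention;
  series from sources using a different national anchoring should be
  relabeled before input.
* Excess estimates inherit whatever incompleteness the recent raw weeks
  have; the completeness cutoff is the user's responsibility.
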