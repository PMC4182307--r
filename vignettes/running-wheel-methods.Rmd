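---
title: "Methods: home-cage running-wheel phenotyping with runwheel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: home-cage running-wheel phenotyping with runwheel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runwheel)
```

## The measurement and the statistic

A free-spinning wheel in the home cage, read nightly by a magnet-and-reed-
switch bicycle odometer, turns voluntary running into four daily numbers per
mouse: **distance** (revolutions x wheel circumference, 0.378 m), **time
spent running** (continuous wheel activity, where "continuous" means no
inter-rotation gap longer than 5 s), **average speed** (distance/time over
the 24 h window) and **maximum speed**.  In SOD1-G93A-like models of motor
neuron disease these metrics decline weeks before overt clinical signs, so
the package's central statistic is an early readout of motor dysfunction:
per animal and metric, *the age at which the metric first falls to 80% of
its baseline and stays there*.

`onset_fit()` implements the estimator in two declared steps:

1. **Baseline** (`rolling_baseline()`): the running peak of a 7-day rolling
   mean over non-censored days.  The 20%-decline rule needs a reference; a
   single-day maximum would be set by upward noise spikes and make the
   threshold unreachable, while a window mean tracks the animal's sustained
   best.  The window (7 d) and mode are configurable.
2. **Sustained crossing** (`detect_decline_onset()`): the first age, after
   the baseline day, at or below `(1 - 0.20) x baseline` on that day and the
   next 2 evaluable days (persistence 3).  Daily data are noisy; requiring
   three consecutive evaluable days suppresses one-night dips.  The crossing
   day itself is reported.  Censored days are skipped, never interpolated.

For the weekly rotarod the same 20% rule is applied to best-of-two latencies
against the animal's post-training baseline (default: best latency in the
first test week), with a single confirmation at the next test instead of a
3-day persistence -- weekly tests are already best-of-two, and a 3-week
persistence would delay onset by most of the effect size.  The 5 s recording
floor is treated as a left-censoring value.  Clinical onset is the first age
at which enhanced tremor and defective hind-limb splay are both present;
peak-weight age breaks ties toward the earliest age.

Whether any smoothing or persistence preceded the original 20% calls is not
stated in the source protocol; both are therefore explicit, configurable
conventions here, and the defaults above are used everywhere in the package.

## The synthetic cohort generator

No raw event data are deposited anywhere, so the package carries a
first-class generator (`simulate_cohort()`) whose *defaults are the study
conditions*: cohorts of 15 females, observed from weaning-age recruitment,
with sporadic hardware censoring at 0.23 days/mouse.

**Disease course.**  Each animal realizes changepoint ages from Normal
draws (`draw_changepoints()`), and two piecewise log-linear capacity
channels (`capacity_at_age()`) shape its activity:

* a *bout* channel (how much it runs): juvenile ramp to a peak near 40 d,
  first decline to a plateau fraction by 60 d, plateau, second decline from
  ~100 d, cessation by ~130 d;
* a *speed* channel (how fast it runs within bouts): same ramp, but its
  first decline starts `speed_lag_days` (3 d) after the bout channel's and
  its plateau fraction is held until ~120 d before the final fall.

Distance is the product of the two channels.  The lag is identifiable from
the printed onset ages alone: because distance = time x speed, the decline
rates of time and speed add for distance, and simultaneous channel declines
would force the distance onset a full harmonic-mean step ahead of the other
two -- earlier than the published 1.2-day gap.  A ~3-day speed lag
reproduces the observed ordering (distance 44.3 d, time 45.5 d, average
speed 47.1 d).

**Within a night** activity is a Poisson number of bouts placed in the 12 h
dark phase, log-normal bout durations (mean 110 s), and per-bout speeds
`v_top x Beta(a, 1)` whose mean tracks the speed channel.  The Beta(a, 1)
family is the load-bearing choice: its density is positive at 1 for any
`a`, so the *nightly maximum* speed stays near the animal's top speed even
while the *mean* declines -- which is exactly the published dissociation
(maximum speed constant at 2.8-3.5 km/h until ~120 d while average speed
falls from ~40 d).  Note the 2.8-3.5 band is a cohort-level property of the
daily maximum (the per-day maximum over animals); the per-day *mean* of
animal maxima drops below it late in disease as bout counts shrink.
Revolution timestamps are then laid down at intervals of
circumference/speed with 5% multiplicative jitter, and every simulated day
is pushed through the same odometer code (`daily_metrics()`) that analyses
real event tables.  A `resolution = "bouts"` fast path computes the daily
metrics from bout-level sums directly (identical up to revolution-level
jitter) for large simulation studies.

**Wild-type course.**  The bout channel ramps to a peak near 29 d then
drifts down by 0.12%/day; the speed channel keeps improving slowly
(`1 - 0.027 e^{-(t - peak)/20}`).  Because the speed improvement initially
outweighs the drift, distance peaks ~2 days after time -- matching the
published peak days (29 for time, 31 for distance) -- and speeds never show
an early peak.  Scales are set so the post-peak plateau means are
15.07 km/day and 5.06 h/day.

**Calibration.**  Free constants that the source never states (plateau
fractions per channel, the speed lag, night-to-night and between-animal
CVs, nominal bout count, rotarod decline-day distribution) were fixed once
by matching the generator's output to the published anchors -- plateau
means, onset means 44.3/45.5/47.1 d, the 2.8-3.5 km/h maximum-speed band,
rotarod onsets 55.1 d (no wheel) / 65.8 d (wheel), censoring 0.23
days/mouse -- and are documented defaults of `wheel_preset()`.  They are
calibration knobs, not measured facts; intra-night bout structure in
particular is an invented stand-in, and nothing downstream should be read
as evidence about real bout statistics.

**Seeding.**  The master seed spawns one deterministic substream per animal
(`animal_seed()`), so cohorts are bit-reproducible and extensible without
disturbing existing animals.

## Odometer conventions

* A gap of exactly 5 s is continuous (the rule is read inclusively).
* A bout's running time is its span (last minus first revolution); a
  single-revolution bout contributes zero time.  A `"span+1"` alternative
  (adding one nominal interval per bout) is available.
* Average speed on a zero-time day is missing, not 0, to avoid biasing
  declines.
* Maximum speed is estimated per bout -- the median of the bout's
  instantaneous speeds and its average speed, daily maximum over bouts.  A
  daily maximum over short rolling windows (e.g. a 5-revolution median) was
  rejected: with ~40,000 revolutions per healthy night it is an
  extreme-value statistic whose upward bias grows with activity level and
  jitter, large enough to push healthy nights well outside the observed
  2.8-3.5 km/h band.
  Bout-scale smoothing is stable across activity levels and makes the
  event-stream and bout-level simulation routes agree.  With every bout
  spanning more than one revolution, the daily average speed (a
  span-weighted mean of per-bout averages) can never exceed this maximum.
* Units are fixed: metres for circumference, km for distance, hours for
  time, km/h for speeds.

## Reproducibility statistics and power

`summarize_study()` reports n, mean, sample SD and CV (100 x SD/mean) over
animals with observed onsets; censored animals are excluded from summaries
but contribute risk-time to the product-limit onset curves
(`onset_survival_curve()`, delegated to the survival package, as is the
log-rank test).  `between_study_cv()` is the SD of per-study means over
their mean -- the headline reproducibility figure (2.2-3.8% across seven
control cohorts).  Display rounding is 1 decimal; computation is full
precision.  One published cell (study 1, distance, CV 7.4) disagrees with
its own printed mean and SD (which give 7.5) -- presumably computed from
unrounded raw data -- and is knowingly not forced to match.

`power_two_sample_t()` evaluates the exact noncentral-t power (df
`2n - 2`, noncentrality `(delta/sd) sqrt(n/2)`), two-sided alpha 0.05 by
default; the original software's sidedness setting is unstated, and the
two-sided convention reproduces all three printed group sizes (4 for
distance SD 3.93, 5 for time SD 4.84, 14 for a rotarod-like SD 9.1).
`min_group_size()` searches the monotone power curve;
`monte_carlo_power()` is the simulation oracle used in tests.

`rank_compare_metrics()` implements tie-corrected Kruskal-Wallis with
Dunn's pairwise z and a Bonferroni correction across the three pairs (the
family-wise scheme behind "Dunn's multiple comparisons" is not specified;
Bonferroni is the conservative reading).  Worth knowing: with n = 15 and
the published spreads, the ~2.5-day distance-vs-average-speed gap has
pairwise power well below one half at the corrected level, so a single
cohort should not be expected to reproduce the published p < 0.01 -- the
tests check the direction of the effect and the oracle arithmetic, not a
power level the design cannot deliver.

## Problem sizes and numerical choices

Simulation-based checks in the test suite use the cohort sizes of the
study design (n = 15; 130-day windows) where the claim is about those
conditions, and deliberately smaller designs elsewhere: the log-rank
type-I calibration runs 150 replicate pairs of n = 8 cohorts over a 47-day
window at bout resolution, and changepoint-recovery uses 200 synthetic
daily series.  Two-sigma bands around stochastic anchors use the simulated
cohort's own standard error.  Degenerate inputs are defined, not patched:
empty event series give zero distance/time and missing speeds; all-censored
series are rejected with an error naming the problem; ties in peak weight
break to the earliest age; truncated-Normal changepoint draws are resampled
until ordered (deterministic fallback to the means after 50 tries).

## Limitations

The generator reproduces daily-summary statistics, not real intra-night
behaviour; censoring is independent thinning, not correlated hardware
failure; there is no litter structure, sex effect, or body-weight coupling
to running; rotarod series are simulated directly at the weekly level
rather than derived from a motor-capacity model shared with the wheel.
Passing calibration tests therefore validates the pipeline's mechanics on
data with the published structure -- it is not evidence about the biology
of any real cohort.
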