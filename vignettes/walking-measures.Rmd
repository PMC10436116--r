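---
title: "Digital walking measures: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital walking measures: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the measurement model, the tunable parameters and why their defaults are
what they are, what the synthetic cohort generator does and does not
emulate, and the numerical and design choices made where the problem was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. The measurement model

The raw input is a step count per 10-second, non-overlapping epoch, per
participant and per device, together with a worn/not-worn flag. Wear
detection is upstream of this package: the flag is consumed as data, never
inferred. Timestamps are epoch *starts*, and the epoch `[t, t+10)` belongs
to the calendar day containing `t` (half-open convention, so a midnight
epoch is counted once). Day boundaries use local midnight of a
configurable timezone, default UTC, since the daily aggregation convention
is otherwise underdetermined.

### Walking bouts

An epoch *qualifies* as walking when it contains at least
`walk_threshold = 6` steps (0.6 steps/s — a deliberately permissive floor
that excludes incidental shuffling). A bout is a maximal chain of
qualifying epochs in which consecutive qualifying epochs are separated by
at most `max_gap = 20` s of non-qualifying time (two empty epochs), kept
when it contains at least 3 qualifying epochs **and** spans at least
`min_duration = 30` s. Both conditions are enforced: a two-epoch run
stretched past 30 s by a bridged gap is still rejected. Bout duration is
the span from the first qualifying epoch to the end of the last one,
*including* bridged gaps — a merged series is one bout, and its natural
duration is its span. Missing epochs in the record count as non-qualifying
wall-clock time, so the gap rule operates on time, not on row adjacency.

### The nine daily measures

Per participant-day-device: daily step count (sum over all epochs); number
of bouts; short bouts (span in [30 s, 60 s)); long bouts (≥ 120 s) — bouts
in [60 s, 120 s) count toward the total only; bout-duration mean, SD
(undefined with fewer than two bouts) and 95th percentile; peak 30-minute
cadence; peak 30-minute pace. Undefined bout statistics are `NA`, never
zero: a day without bouts has no bout-duration mean. Two auxiliary
quantities drive filters: wear time (worn epochs × 10 s) and ambulatory
time, defined as time in *qualifying epochs* rather than time in bouts —
the broader of the two readings, chosen because sub-bout walking is still
ambulation; it is configurable via the bout interface if a bout-restricted
variant is wanted.

**Peak 30-minute cadence** is the mean cadence over the day's 180
highest-count epochs (not necessarily contiguous). Days with fewer than
180 recorded epochs are implicitly zero-padded: the denominator is always
1800 s, preserving comparability of the fixed 30-minute window across days
with different wear.

**Peak 30-minute pace** multiplies that cadence by an estimated step
length, `k × height`, with the conventional anthropometric fractions
`k = 0.413` (female), `0.415` (male), and their midpoint `0.414` when
gender is unspecified. The source definition names only "gender and
height"; these constants are the standard convention, are configurable in
`peak30_pace()`, and are recorded in the JSON report metadata. Pace is
`NA` without a height.

**95th-percentile bout duration** ("highest bout duration below the top 5%
longest bouts") is an empirical quantile. With typical daily bout counts
(tens), any quantile convention sits between the same two order statistics;
we use linear interpolation (R's default type 7) and expose the `type`
argument, so the choice is explicit and changeable rather than silent.

## 2. Accuracy characterization

Participant-days enter the accuracy analysis when **both** devices have a
record that day, each with ≥ 8 h wear and strictly more than 100 steps.
Missing values are dropped *pairwise per measure* (a zero-bout day has no
bout-duration SD but a perfectly valid step count), not listwise.

**Fisher ICC.** The primary agreement statistic is the classical
intraclass correlation for paired readouts entered symmetrically: with
grand mean `m` and pooled variance `s²` of the 2n values,
`ICC = Σ(x−m)(y−m) / (n s²)`. It is exactly symmetric under swapping the
members of any pair, equals the Pearson correlation of the doubled data
(the independent oracle in the tests), returns 1 for identical streams and
−1 for two perfectly anti-ordered pairs. A one-way ANOVA mean-square form
`(MSB − MSW)/(MSB + MSW)` is available as `type = "anova"` for sensitivity
analysis; the two agree to O(1/n).

**Confidence intervals** are percentile bootstrap over *participants*:
clusters are resampled with replacement carrying all their days, 1000
replicates by default, because repeated days from one participant are
correlated and day-level resampling would understate the variance.
Percentile (rather than BCa) is the minimal-assumption default. Replicates
on which a statistic is undefined (e.g. a zero-variance resample for a
correlation) are redrawn with a capped retry budget; the cap makes
degenerate inputs fail loudly rather than loop.

**Pearson p-values** are two-sided and treat participant-days as
independent; that caveat is written into the report metadata, since the
clustering makes them anticonservative in principle.

**Bland–Altman** bias and limits of agreement are `mean(d)` and
`mean(d) ± 1.96 sd(d)` for `d = study − reference`. The point set uses the
*reference* value on the x-axis (a "modified" Bland–Altman): when one
instrument is a designated low-error truth source, plotting against the
pair mean would mix device error into the abscissa.

One numerical choice is visible in the perfect-device limit: when
`study = reference + c` the Pearson r is set to exactly 1 by shift
invariance instead of letting `cor()`'s square-root round-off return
1 − 1e−16, so the noiseless limit is machine-exact.

## 3. Time to reliability

The question: over how many days must a daily measure be averaged before
the average is a stable characteristic of the person? For each aggregation
scope `k` (1–30 days), each participant contributes the pair (mean over
window A, mean over window B) for adjacent non-overlapping k-day windows
anchored at their own first observed day plus an offset; a Fisher ICC is
computed across participants at each offset; offsets shift by one day.

Design choices where the procedure was underdetermined:

* **Eligibility.** A participant enters at scope `k` and offset `o` when
  both windows contain at least `⌈0.5 k⌉` days with ≥ 12 h wear. The
  50%-of-days and 12-h bars are the source procedure's; both are
  parameters.
* **Window means** are taken over the days meeting the 12-h bar (and with
  a non-null measure value), not over all days: the 50% rule implies
  sub-threshold days exist inside valid windows, and including their
  partial-wear readouts would bias window means downward. An all-days
  variant is a one-line change via the wear bar parameter.
* **Combining offsets: mean of per-offset ICCs**, each offset contributing
  one pair per eligible participant — rather than pooling all pairs into
  one ICC. Pooling would overweight long-wearing participants and feed
  heavily overlapping (hence correlated) pairs into a single estimator;
  averaging keeps each ICC internally balanced. Offsets with fewer than
  two eligible participants are skipped.
* **Anchoring** is per-participant (own first day + offset), not
  calendar-aligned: wear spans are individual, and the procedure is about
  within-person stability, not calendar effects.
* **CIs** bootstrap participants through the whole offsets-and-averaging
  procedure (200 replicates by default at curve scale; configurable). The
  weighted-ICC implementation makes a replicate a set of matrix products,
  so full curves with CIs stay cheap.
* **Peak 30-minute pace is excluded** by default: it is a deterministic
  per-participant rescaling of peak cadence, so its curve would duplicate
  the cadence curve.

The time to reliability is the smallest scope whose ICC meets the 0.75
threshold (a parameter). Under the two-variance-component model the curve
is the Spearman–Brown form `ICC(k) = σ²_b/(σ²_b + σ²_w/k)`, crossing the
threshold at `k* = 3 σ²_w/σ²_b`; the acceptance suite recovers the curve
from simulated cohorts within Monte Carlo error. One honest caveat: when
`3 σ²_w/σ²_b` is an integer the theoretical curve touches 0.75 *exactly*
at `k*`, so the empirical first crossing on any finite cohort is a coin
flip between neighbouring scopes; the tests assert exact recovery only
when the crossing clears the threshold by more than the Monte Carlo SE,
and otherwise require the recovered scope's theoretical ICC to lie within
3 SE of the threshold. This is a property of the estimand, not of the
implementation.

## 4. The synthetic cohort generator

`simulate_cohort()` emulates what the analyses assume about real cohorts:

* a per-participant activity level `b_i ~ N(0, σ²_b)` and a day effect
  `e_id ~ N(0, σ²_w)` set each day's step target
  `mean_daily_steps + b_i + e_id` (truncated at zero);
* walking arrives in bouts with log-normal durations and Gaussian
  walking-epoch cadence; bouts are accumulated until the day's target is
  met and scattered uniformly over the wear block, so the realized daily
  total tracks the target to within a few steps and the configured
  variance components are recoverable by one-way ANOVA;
* sparse sub-threshold (1–5 step) incidental epochs;
* wear is a contiguous daytime block with jittered edges, emitted as an
  explicit worn flag;
* both devices observe the same latent stream: the reference with small
  additive truncated-at-zero epoch noise (SD 0.5 steps), the study device
  with larger noise (SD 1.5) plus missed epochs (3%). Truncation at zero
  on mostly-empty epochs makes the study device read *high* on daily step
  count — a systematic positive ME that the accuracy module should and
  does expose. Device error lives at the epoch level because both devices'
  daily measures are recomputed from epochs by the same code path.

Default calibration (chosen once, not tuned to tests): 10,000 mean daily
steps; `σ_b = 1800`, `σ_w = 3900`, so that the total daily-step SD
`√(σ²_b+σ²_w) ≈ 4300` matches a healthy-cohort magnitude and the implied
time to reliability `3σ²_w/σ²_b ≈ 14` days sits in the low-teens; a
7.5–21.5 h wear block (≈ 14 h); 1.7 ± 0.25 steps/s walking cadence;
log-normal bout durations with median 90 s and log-SD 0.8. Heights are
N(1.70, 0.10) m clamped to a plausible range; genders alternate.

What the generator does **not** emulate: weekday/weekend or seasonal
structure, wear-compliance decay, multi-block wear with naps, device drift
or correlated (non-i.i.d.) device error, heteroscedastic error growing
with activity, and any disease-specific gait phenotype. A green test
therefore establishes that the *pipeline* is correct under the stated
two-component model — not that any particular device achieves any
particular accuracy or 16-day reliability on humans; those numbers belong
to real cohorts.

Because closed-form targets (Spearman–Brown recovery, bootstrap coverage)
require the variance decomposition to hold *exactly* on daily totals —
and because epoch-materializing a 200 × 64-day cohort is needlessly heavy —
the module also ships day-level generators: `simulate_daily_cohort()`
(daily totals `mean + b_i + e_id`, constant wear) and
`simulate_paired_days()` (adds a constant device bias, a per-participant
device offset, and i.i.d. day noise; the participant-level offset is what
makes *clustered* CIs genuinely necessary for nominal coverage). The
acceptance suite uses these for parameter recovery and coverage, and the
epoch-level generator everywhere the full pipeline is in play; its own
ANOVA recovery is tested at 120 × 12 scale to stay inside the runtime
budget.

## 5. Degenerate inputs and determinism

* Fewer than 2 pairs, or zero pooled variance: ICC/Pearson are `NA` with a
  warning — undefined, never coerced to 0 or 1.
* Bootstrap with fewer than 2 clusters: `NA` interval.
* Reliability at a scope no participant can fill: `NA` with cohort size 0.
* All randomness (generators, bootstraps) is seeded, and seeded code paths
  save and restore the caller's RNG state; identical (seed, input) gives
  byte-identical outputs end to end, which the acceptance suite checks at
  the file level.

## 6. Known limitations

* Wear detection is out of scope; garbage worn flags give garbage wear
  filters.
* The Pearson p-values ignore clustering (documented, matching common
  practice in device-agreement reports).
* The adjacent-window ICC averages per-offset estimates; other defensible
  aggregations (pooling, median) would differ slightly in small cohorts.
* Calendar-day aggregation splits activity at midnight; shift workers need
  a non-default timezone or a custom day boundary.
* The pace step-length constants are a population-level convention; no
  claim is made about individual gait.
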