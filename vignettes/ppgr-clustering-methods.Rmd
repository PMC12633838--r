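---
title: "Methods: CV-threshold clustering of postprandial glycemic responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CV-threshold clustering of postprandial glycemic responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgrclust)
```

## The problem

A continuous glucose monitor (CGM) samples interstitial glucose every
5 minutes. After a meal, glucose rises and falls over roughly four hours
— the postprandial glycemic response (PPGR). In type 1 diabetes the
shape and height of that excursion depend on the meal, the insulin dose
and timing, and the individual's physiology; carbohydrate grams alone
predict it poorly. What *is* observed is intra-individual
reproducibility: a person's habitual meals tend to elicit recurring
response shapes. `ppgrclust` makes that reproducibility measurable: it
isolates an individual's PPGRs per meal category and groups the ones
that are statistically indistinguishable at a clinically motivated
variability bar.

## Isolating PPGRs

A PPGR is the half-open 4-hour window from a candidate start, gridded at
the 5-minute CGM cadence — 48 slots, offsets 0–235 min. Candidate starts
are:

* reported meals;
* imputed mealtimes (below);
* meal-related boluses on band-days with no meal at all.

A bolus is *meal-related* when it falls within −4 min to +4 h of a
reported meal, otherwise it is a *correction*. Each calendar day
contributes at most one event per meal band (breakfast 06:00–10:00,
lunch 10:00–14:00, snack 14:00–18:00, dinner 18:00–22:00; half-open
intervals, so 10:00 is unambiguously lunch); when several candidates
compete, a reported meal beats a mealtime bolus beats an imputed start,
and the earliest wins among equals. Further reported intake in the *same*
band inside the window adds its carbohydrates to the event rather than
starting a new one; a meal in a *different* band does start its own
event (otherwise a band could never contain an event on a day whose
previous band's window overruns it). Windows retaining fewer than 24 of
their 48 slots are excluded and counted. Gaps inside retained windows
stay missing — no interpolation — and every downstream statistic uses
available points only.

Mealtime imputation targets (week, weekday, band) cells with neither a
reported meal nor a meal-related bolus: if the same weekday's band holds
reported meals in other weeks, an imputed start is placed at their mean
clock time, rounded to the 5-minute grid, with unknown carbs. Weeks are
counted from the record's first day (`floor(days since start / 7)`), so
records starting midweek keep full cells.

Samples are snapped to the window grid by nearest slot; with a CGM
cadence of 5 minutes this is exact whenever meals are logged on the
minute grid, and off-grid mealtimes displace samples by at most
2.5 minutes. Each window is also *peak-centered* (maximum subtracted, so
the centered series attains 0 exactly) for curve comparison and
reporting; the clustering statistic below deliberately uses the raw
values.

## The cohesion statistic

For one participant and band, let μ be the mean of **all** glucose
values pooled over every retained event of that category — computed once,
before clustering, outliers included. The CV of any event set *S* is

$$\mathrm{CV}(S) = 100\cdot\frac{\sigma(\text{pooled values of } S)}{\mu}\,\%$$

with σ the sample (n−1) standard deviation. Two deliberate choices:

* **Raw values, not peak-centered ones.** The reference μ is a mean of
  glucose concentrations; peak-centered series are ≤ 0, which would make
  the ratio ill-defined. Centering serves cross-comparison of curve
  shapes, not the cohesion statistic. (The choice is isolated in
  `event_cv()`/`pooled_cv()`, which read `events$glucose`.)
* **Pooled SD, not a mean of per-event CVs.** The cluster-level
  "internal CV" reported in evaluation is defined on the combined
  glucose values, so cluster growth tests the same quantity that is
  later reported.

The statistic is scale invariant (rescaling all glucose rescales σ and μ
alike), which the suite asserts.

## The clustering algorithm

Within one participant × band, with threshold *T* (default 36 %):

1. Order events chronologically (event id breaks ties). All later steps
   are deterministic, so any presentation order yields the same result.
2. Seed a cluster with the earliest unassigned event; sweep the
   remaining unassigned events in order, adding any whose inclusion
   keeps the pooled CV < *T*; re-sweep until a full pass adds nothing
   (closure, not a single pass). Commit the cluster if it has ≥ 2
   members; otherwise set the seed aside as tentative (still available
   to later clusters).
3. When no seed can form a multi-member cluster, tentative events form
   the outlier group. A seed that attracts no partner is an outlier, not
   a singleton cluster.
4. Multi-membership resolution, against compositions frozen at step 3:
   every event — outliers included — eligible for two or more clusters
   (pooled CV < *T* on hypothetical inclusion; current membership counts)
   moves to the largest eligible cluster, ties to the earliest formed.
5. Repair: a cluster pushed to CV ≥ *T* by moves sheds, one at a time,
   the member whose removal lowers its pooled CV the most (ties: latest
   added), until it is back under *T*; shed events and clusters reduced
   below two members join the outlier group.

The returned object always satisfies two invariants, re-asserted on
every run: each non-outlier cluster has ≥ 2 members and pooled CV < *T*,
and the clusters plus the outlier group partition the input events.

### Numerical notes

Pooled CVs are computed from per-event (count, sum, sum of squares)
triples, so growth sweeps cost scalar arithmetic rather than
re-concatenation; a guard clamps the tiny negative variances that
floating-point cancellation can produce for near-constant sets. The
exhaustive test oracle instead concatenates values and calls `sd()`,
keeping the two routes independent; they agree to 10⁻⁹ in the suite.

### Saturation: why large clusters can absorb anything

Adding one foreign event at mean distance *d* to an *n*-member pure
cluster adds mixture variance $\frac{n}{(n+1)^2}d^2$, so blocking the
addition requires roughly $d/\mu \ge 0.36\,(n+1)/\sqrt{n}$. Since
glucose is positive, $d/\mu < 2$, and the inequality must fail once
*n* exceeds ≈ 28 — **no** separation keeps a sufficiently large cluster
from absorbing single foreign events under a pooled-CV rule. This is a
property of the method, not a bug: the CV of a large cluster is barely
moved by one event. Consequently exact recovery of planted structure is
only a meaningful expectation when per-template event counts are modest
(below roughly a dozen for well-separated two-template categories), and
three equally spaced templates cannot be made pairwise non-mergeable at
all once the middle level sits near μ. Validation regimes are sized
accordingly (below).

## Evaluation and statistics

Per cluster: pooled sample SD; SE = SD/√(number of events); internal CV
(the pooled CV, re-asserted < *T* at reporting time); peak and
carbohydrate mean/SD (carb statistics skip unknown-carb events and
report the count used); and a flag comparing SE with the CGM sensor
error (0.8 mmol/L, a named constant with a config override). Per-offset
curves give mean, SD and SE across members at each of the 48 offsets,
with counts reflecting missing slots. Outlier-group metrics are reported
in dedicated columns, never mixed into cluster means.

The carbohydrate ANOVA is implemented from the sums-of-squares
definitions with an F-tail p-value — its arithmetic is part of the
package's test surface and is cross-checked against `anova(lm(...))`.
Eligible groups are the known-carb values of each non-outlier cluster
plus the outlier group when non-empty; fewer than two eligible groups
yields an explicit skip marker rather than an error, mirroring the
report notation for single-cluster categories. No multiple-testing
correction is applied across participant × band tests, and no post-hoc
tests are run.

The effect-size solver inverts the exact two-sample t-test power
function — noncentral t with df = 2n − 2 and noncentrality d·√(n/2) —
by bracketed root-finding, refined until the attained power is within
10⁻⁸ of the request. At n = 12 per group, two-sided α = 0.05 and power
0.80 it returns d = 1.1968 (4 d.p.); the suite also verifies a solved
value against a 200 000-replicate Monte-Carlo power estimate.

## The synthetic generator

`simulate_participant()` emulates the data the method consumes:

* a full 5-minute grid over the span (default 8 weeks) at a baseline
  glucose level, with i.i.d. Gaussian sensor noise (`noise_sd`, default
  0.25 mmol/L);
* per band, a small library of response templates — linear rise to
  `baseline + amplitude` at `time_to_peak`, then exponential decay with
  `decay_halflife` (the value one half-life past the peak is baseline +
  amplitude/2). Analytic curves keep oracle values closed-form;
* each band-day draws a template via a **balanced rotation** (a seeded
  permutation of an evenly stocked multiset), emulating a habitual menu
  repertoire cycled over the span. Besides realism — free-living eating
  is habitual, not i.i.d. — balance keeps planted cluster sizes
  near-equal, which the saturation analysis above shows is what makes
  exact recovery a fair expectation;
* mealtimes on the 5-minute grid, jittered up to `mealtime_jitter`
  minutes in 5-minute steps (so the noiseless limit reproduces template
  curves exactly); carbs drawn per template, truncated at zero; a bolus
  accompanies every meal;
* with probability `p_missing_mealtime` a meal log is suppressed while
  its bolus and glucose remain — the orphaned bolus classifies as a
  correction, so the band-day becomes exactly the imputation case;
* with per-day probability `p_sensor_dropout`, a contiguous run of 30–60
  samples is deleted, exercising the < 24-point exclusion.

Everything derives from the mandatory seed (participant *i* uses
`seed + i`), so records are bit-reproducible.

What the generator does **not** model: insulin–glucose dynamics, carb
absorption kinetics, circadian baseline drift, correlated sensor error,
compression artifacts, or hypoglycemia events. Passing recovery tests
therefore demonstrates that the algorithm recovers planted repeated
shapes under realistic logging imperfections — not that real CGM data
contain such clean structure.

### Validation regimes and problem sizes

* *Constraint suite*: 108 participant × band instances (1-week records,
  1–3 templates, 10 % missing logs, 10 % dropout days) — every output is
  checked for the CV bound, the partition property, order invariance and
  seed determinism.
* *Oracle suite*: micro-instances of ≤ 6 events against exhaustive
  enumeration of all set partitions (Bell(6) = 203), maximizing assigned
  events under the CV constraint; greedy must match whenever the
  oracle's maximal feasible partition is unique.
* *Well-separated recovery regime*: 2 templates per band with baselines
  2.5 and 16 mmol/L, amplitude 1.2, noise SD 0.25, 2-week span (≈ 7
  events per template), no missing logs or dropouts. Empirically (and by
  the blocking inequality) same-template pooled CV stays below 25 % and
  cross-template pooled CV above 45 %; the suite requires the planted
  cluster count and adjusted Rand index > 0.9 in ≥ 95 % of 20 seeds.
  The 2.5 mmol/L baseline is hypoglycemic — the regime is a separation
  stress case, not a physiological claim.
* *Degenerate regime*: one template, zero noise — exactly one cluster
  and zero outliers per band.

These sizes keep the default test run fast while exercising every stage;
they are choices of this package, documented here so they can be scaled
up for sensitivity analyses.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `threshold` | 36 | % | CV cohesion bar; the clinical glycemic-variability threshold. Configurable for sensitivity analyses. |
| `window_minutes` | 240 | min | PPGR window length (gastric emptying completes within 4–5 h). |
| `cadence_minutes` | 5 | min | CGM grid spacing. |
| `min_points` | 24 | samples | Minimum retained window content (2 h of data). |
| `bolus_pre_minutes` | 4 | min | Pre-meal slack for meal-related boluses. |
| `sensor_error` | 0.8 | mmol/L | CGM reference error for the SE comparison. |
| `include_snack` | `FALSE` | — | Snack events are isolated but excluded from clustering/reporting by default. |

Internally everything is mmol/L (mg/dL inputs divide by the named
constant 18.016); timestamps are naive local clock times — meal bands
are defined on the wall clock, so no timezone arithmetic is ever
applied.

## Degenerate inputs and tie-breaks

Empty glucose series isolate to an empty event set with a report, not an
error. Duplicate CGM timestamps keep the first sample after the
canonical sort (deterministic and order-independent), with a warning.
Constant event sets have CV 0 and always cluster together. Equal-merit
shedding candidates in repair drop the latest-added member; equal-size
reassignment destinations prefer the earliest-formed cluster; candidate
starts tie-break by class priority then time. Empty bands produce report
rows of explicit nulls.

## Known limitations

* The pooled-CV rule saturates for large clusters (analysis above):
  with many events per recurring meal, distinct but adjacent response
  levels will merge. A per-event membership criterion or a cap on
  cluster contribution would change this, at the cost of departing from
  the pooled definition of cluster cohesion.
* Whether clustering "should" consume raw or peak-centered series is a
  genuine modeling fork; this package pins raw values for the
  well-definedness reasons given, behind a single switch point.
* Imputation assumes weekly routine; it will fabricate plausible but
  possibly false starts for genuinely skipped meals (the glucose filter
  then decides retention).
* The ANOVA treats events as independent; repeated events within a
  participant violate that mildly, as in the clinical analyses this
  mirrors.
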