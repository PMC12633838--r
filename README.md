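# ppgrclust

Meal-based clustering of postprandial glycemic responses (PPGRs) from
continuous glucose monitor (CGM) data.

People with type 1 diabetes respond to meals in ways that carbohydrate
content alone does not predict, yet an individual's responses to their
habitual meals tend to be reproducible. `ppgrclust` turns raw 5-minute
CGM traces plus meal/bolus logs into per-meal response windows and groups
the windows that an individual's body treats as "the same response",
giving clinicians and researchers a compact, personalized picture of
glycemic reproducibility — the groundwork for response prediction and
meal-time insulin planning.

## Method

For one participant and one meal category (breakfast 06:00–10:00, lunch
10:00–14:00, snack 14:00–18:00, dinner 18:00–22:00, half-open clock
intervals):

1. **Isolation.** Every reported meal, imputed mealtime, or meal-related
   bolus starts a 4-hour window (48 readings at 5-minute cadence).
   Boluses within −4 min to +4 h of a logged meal count as meal-related;
   all others are corrections. Windows with fewer than 24 readings are
   excluded; further same-category intake inside a window merges into it.
   Missing mealtimes are imputed from the same weekday band in other
   weeks. Each window is also peak-centered (peak value subtracted) for
   curve comparison.
2. **Cohesion statistic.** With μ the mean of *all* glucose values over
   the participant's retained PPGRs in the category, the CV of any event
   set is

   CV = 100 · σ(pooled glucose values) / μ  (%)

   where σ is the sample standard deviation.
3. **Clustering.** A greedy pass over chronologically ordered events
   grows clusters that keep pooled CV < 36 % (the clinical glycemic
   variability threshold); events that fit nowhere become outliers, and
   events eligible for several clusters go to the largest.
4. **Evaluation.** Per cluster: SD, SE = SD/√(n events), internal CV,
   peak and carbohydrate summaries, and a comparison of SE against the
   0.8 mmol/L CGM sensor error. Per category: a one-way ANOVA of
   carbohydrate intake across cluster labels, and a noncentral-t power
   solver for the design effect size.

A synthetic CGM generator with planted per-category response templates
(known ground truth) lets every stage be validated without restricted
clinical data; recovery is scored by adjusted Rand index.

## Worked example

```r
library(ppgrclust)

cfg <- sim_config(participants = 1, weeks = 2, seed = 42)   # 2 planted
res <- simulate_participant(cfg, 1)                         # templates/band
rec <- with_imputed_meals(res$record)   # classify boluses + impute mealtimes
iso <- isolate_ppgrs(rec)
iso$events
#> <ppgr_events: 42 events>
#> breakfast    dinner     lunch
#>        14        14        14

be <- iso$events[iso$events$band == "breakfast", ]
cs <- cluster_category(be)              # CV < 36% greedy clustering
cs
#> <cluster_set S01/breakfast: 2 cluster(s), 0 outlier(s), threshold 36%>
#>   cluster 1: 7 events, pooled CV 15.21%
#>   cluster 2: 7 events, pooled CV 4.44%

do.call(rbind, lapply(cs$clusters, cluster_metrics,
                      events = be, context = cs$context))
#>   cluster_id n_events    sd    se internal_cv peak_mean carbs_mean ...
#> 1          1        7 1.458 0.551       15.21     17.37       58.2
#> 2          2        7 0.425 0.161        4.44      3.92       24.4

recovery_score(res$truth, cs, be)       # adjusted Rand index vs truth
#> [1] 1
carb_cluster_test(cs, be)
#> one-way ANOVA: F(1, 9) = 57.92, p = 3.291e-05
```

Both planted breakfast templates are recovered exactly (ARI = 1): two
7-event clusters whose pooled CVs (15.2 % and 4.4 %) sit well under the
36 % cohesion bar, whose standard errors (0.55 and 0.16 mmol/L) fall
below the 0.8 mmol/L sensor error, and whose carbohydrate means differ
significantly — the planted high-amplitude template came with larger
meals.

An end-to-end run (events → assignments → cluster summary → report table
→ ANOVA → curves → manifest) is one call:

```r
run_pipeline(list(input = list(simulate = list(participants = 2,
                                               weeks = 2, seed = 7)),
                  out_dir = "out"))
```

Real data enter through `read_ohio_xml()` (per-participant XML with
`glucose_level`/`meal`/`bolus` event streams, mg/dL converted to mmol/L)
or `read_events_csv()` (generic headered CSV). A thin CLI wrapper lives
at `inst/cli/ppgrclust` (`run` and `simulate` subcommands).

## Documentation

See the methods vignette (`vignettes/ppgr-clustering-methods.Rmd`) for
the model, its assumptions, parameter defaults, numerical choices, and
known limitations.
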