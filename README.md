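# mobagree

Agreement between GPS-derived and self-reported daily mobility indicators.

## The problem

In health and aging research, two daily mobility indicators are widely used
to characterise how much older adults participate in out-of-home life:

- **TOH** — *time out of home*: the total daily duration spent outside a
  circular buffer around the residence, in minutes;
- **#ALs** — *number of activity locations*: the daily count of stationary
  out-of-home visits (shopping, social visits, sports, ...).

Both can be measured with paper travel diaries (self-reports, "REP") or
derived from wearable GPS tracking ("GPS"). Neither source is ground truth:
diaries suffer omission, rounding and recall error; GPS suffers signal loss,
positional noise and unworn devices, and its indicators depend strongly on
the extraction thresholds. `mobagree` implements the full comparison
pipeline between the two sources and the threshold sensitivity analysis
that goes with it, for researchers validating sensor-based mobility
indicators against self-reports.

## What the package computes

**GPS event extraction.** Fixes are speed-filtered (> 330 km/h removed),
split into days at midnight, and days with a registration period under 9 h
discarded. The geocoded home is validated with DBSCAN (haversine metric,
eps = 60 m, minPts = 3) over the first-morning/last-evening fixes of valid
days and must lie within 150 m of a cluster centre. Three thresholds govern
event extraction:

- `Tmin` — minimum event duration (default 6 min),
- `Dmax` — home-buffer radius and maximum spatial extent of a stop
  (default 125 m),
- `Tmax` — maximum temporal gap bridged by event-level interpolation
  (default 300 min).

TOH events are maximal out-of-home episodes of the home/out-of-home fix
labelling, with same-state gaps up to `Tmax` interpolated and episodes
shorter than `Tmin` absorbed into home. Activity locations come from
time-based sequential stop detection (a cluster grows while fixes stay
within `Dmax` of its anchor and gaps stay below `Tmax`; it is a stop when
it spans `Tmin`), followed by merging of stops split by sub-3-min noise
and exclusion of stops within `Dmax` of home.

**Agreement statistics.** Event-level: temporal-overlap matching with 1:1 /
1:n / 1:0 cardinalities, pooled precision/recall/F1, per-participant
interval intersection-over-union (IoU) and the intersection / REP-only /
GPS-only duration decomposition. Day-level, on matched valid days:
descriptive statistics of daily REP − GPS differences with between- and
within-participant SDs and tolerance bands, Bland-Altman limits of
agreement for multiple observations per individual (one-way ANOVA variance
decomposition), one-way interrater ICC with F-based confidence interval,
pooled Spearman correlation and within-person correlations (iCorr).

**Sensitivity analysis.** `agreement_curve()` recomputes F1 and IoU for
both indicators along a grid of any one threshold; `stepwise_optimize()`
reproduces the stepwise procedure (Tmax → Tmin → Dmax → re-confirm Tmin →
re-confirm Tmax) starting from Tmin = 3 min, Tmax = 1 h, Dmax = 100 m.

**Synthetic cohort.** `simulate_cohort()` generates a study week with known
ground truth: home/outing schedules with nested stationary visits, GPS
sampling with Gaussian noise (inflated indoors), bursty indoor signal loss,
device-off windows, and diary errors (omission, start/end shift, clock
rounding). Every downstream stage is validated against this truth.

## Worked example

```r
library(mobagree)

cohort <- simulate_cohort(sim_config(n_participants = 4, n_days = 7,
                                     gps_interval = 30, seed = 2026))
res <- run_pipeline(cohort)

m <- res$manifest
cat(sprintf("fixes: %d (outliers removed: %d), valid days: %d/%d\n",
            m$n_fixes_filtered, m$n_fix_outliers, m$n_valid_days, m$n_days))
cat(sprintf("matched days: TOH %d, #ALs %d\n",
            m$n_matched_toh_days, m$n_matched_al_days))
toh <- res$reports$toh; al <- res$reports$al
cat(sprintf("TOH : F1 %.2f  IoU %.2f  BA %.1f [%.1f; %.1f] min  ICC %.2f\n",
            toh$f1, toh$iou_mean, toh$bland_altman$mean_diff,
            toh$bland_altman$loa_low, toh$bland_altman$loa_high,
            toh$icc$icc))
cat(sprintf("#ALs: F1 %.2f  IoU %.2f  BA %.2f [%.2f; %.2f]      ICC %.2f\n",
            al$f1, al$iou_mean, al$bland_altman$mean_diff,
            al$bland_altman$loa_low, al$bland_altman$loa_high, al$icc$icc))
```

```
fixes: 34705 (outliers removed: 0), valid days: 27/28
matched days: TOH 24, #ALs 22
TOH : F1 0.95  IoU 0.87  BA -6.3 [-66.4; 53.8] min  ICC 0.97
#ALs: F1 0.93  IoU 0.56  BA -1.32 [-4.58; 1.94]      ICC 0.72
```

Reading the output: on the 24 matched TOH days, 95% harmonic-mean event
agreement and 87% durational overlap between reported and GPS out-of-home
time; reported TOH runs 6.3 min below GPS on an average day, with 95%
limits of agreement of about ±1 h. Activity-location counts agree less
well (IoU 0.56, ICC 0.72) — the same qualitative pattern seen with real
cohorts, where counting discrete visits is harder than accumulating
durations.

`run_pipeline()` also accepts a directory of CSV inputs (`gps_fixes.csv`,
`toh_diary.csv`, `al_diary.csv`, `homes.csv`; see `write_cohort()` for the
dialects) and, given `out_dir`, writes `events_gps.csv`,
`daily_indicators.csv`, `match_table.csv`, `homes_resolved.csv`,
`exclusion_log.csv`, `agreement_report.json` and a run `manifest.json`
with counts at every exclusion step.

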