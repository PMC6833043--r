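---
title: "Methods: comparing GPS-derived and self-reported daily mobility indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing GPS-derived and self-reported daily mobility indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mobagree)
```

`mobagree` quantifies the convergent validity of two daily mobility
indicators for older adults — time out of home (TOH, minutes per day) and
number of activity locations (#ALs, visits per day) — measured
independently by travel diaries (REP) and wearable GPS tracking (GPS).
Neither source is treated as ground truth: the package computes symmetric
agreement statistics, plus a sensitivity analysis of the thresholds that
govern GPS event extraction. This vignette documents the model, the
parameters, the numerical conventions, the synthetic cohort used for
validation, and the design choices that were genuinely open.

## 1. GPS processing model

Processing follows seven stages.

1. **Outlier removal.** A forward scan drops any fix whose great-circle
   speed from the last *retained* fix exceeds `vmax_kmh` (default
   330 km/h, the regional high-speed-rail limit). Anchoring on the last
   retained fix — rather than the previous raw fix — removes a burst of
   consecutive jumps entirely, and makes the filter idempotent. All
   distances in the package are haversine on a sphere of radius
   6371.0088 km: sub-metre accurate at these scales and free of any map
   projection dependency.
2. **Day segmentation.** Fixes are assigned to civil dates with a
   half-open day boundary ([00:00, 24:00); a fix at exactly midnight
   belongs to the new day), giving a deterministic partition. Timestamps
   are treated as local civil clock time with no DST modelling, because
   diaries are written in local clock time and must align.
3. **Day validity.** A day is valid when its registration period (first to
   last fix) reaches 9 h; participants need at least 2 valid days.
4. **Home validation.** DBSCAN (haversine metric, eps = 60 m, minPts = 3,
   neighbourhoods counting the point itself) clusters the first-morning
   and last-evening fixes of valid days. Cluster centres are
   coordinate-wise medians — robust, and consistent with the stop
   representation below; the centre statistic was an open choice. Among
   clusters, the one nearest the geocoded address is the GPS home
   candidate; the home is valid when that centre lies within 150 m of the
   address. The address is replaced by the GPS candidate only when the
   candidate captures *strictly* more of the participant's fixes within a
   60-m buffer (equality keeps the address — the conservative reading).
   Ties between equally near clusters go to the larger cluster, then the
   lexicographically smaller centre, for determinism.
5. **TOH extraction.** Fixes within `Dmax` of home (inclusive boundary,
   stated once and reused everywhere a geofence appears) are HOME, others
   OH. Maximal same-state runs become episodes; an inter-fix gap of up to
   `Tmax` flanked by the same state on both sides is interpolated into the
   episode, while longer gaps — or gaps flanked by unequal states — count
   toward neither state. OH episodes shorter than `Tmin` are relabelled
   HOME (not GAP: they fail to qualify as events, but the time was
   observed) and neighbouring HOME episodes re-merged under the same
   `Tmax` rule. No interpolation is performed into unobserved time at the
   day edges. Because days are segmented first, events never span
   midnight; an overnight outing is truncated at 24:00.
6. **AL extraction.** Time-based sequential stop detection: a candidate
   cluster opens at an anchor fix; a subsequent fix joins while it lies
   within `Dmax` of the *anchor* and its gap to the immediately preceding
   fix is at most `Tmax`. When the candidate can no longer be extended it
   closes: a stop if its span reaches `Tmin`, else the anchor advances by
   a single fix. The advance-by-one policy on failure is the canonical
   stay-point formulation; it guarantees that a stop preceded by slow
   movement is still anchored near its true start. A stop is represented
   by the coordinate-wise median of its member fixes (even counts: mean of
   the two middle order statistics, per coordinate) and the interval from
   first to last member timestamp. Moves shorter than 3 min are
   reinterpreted as noise (indoor signal wander), and consecutive stops
   separated only by noise and/or gaps merge when their medians are closer
   than `Dmax` and the inter-stop time is below `Tmax`; merging iterates
   left-to-right to a fixed point, which is deterministic and
   order-insensitive for chains. After merging, member fixes may exceed
   `Dmax` from the original anchor; the spatial constraint binds only at
   clustering time. Stops with medians within `Dmax` of home are excluded;
   the remainder are the activity locations.
7. **Daily aggregation.** TOH durations are summed and ALs counted per
   day; a valid day without events is a genuine zero-mobility day.

### Threshold defaults

| threshold | meaning | default | initial value for optimization |
|---|---|---|---|
| `Tmin` | minimum event duration | 6 min | 3 min |
| `Dmax` | home buffer / stop extent | 125 m | 100 m |
| `Tmax` | maximum interpolated gap | 300 min | 60 min |

The defaults are the plateau values that stepwise sensitivity analyses of
this kind typically select on week-long older-adult cohorts; the initial
values are the literature-typical starting points for such an analysis.

## 2. Diary processing

Reported TOH entries are deleted when outside the study period or lasting
at most 3 min (strict: a 4-min entry survives, a 3-min entry does not).
Reported AL entries are additionally excluded for missing start/end times,
non-stationary activity (a reported movement), taking place at home, or
being a false report; an entry is excluded once but every applicable
reason is logged, so reason tallies may exceed the excluded-entry count.
Overnight entries are split at midnight so daily sums are well defined —
the day boundary is segmented everywhere at midnight, but overnight
reports are otherwise unspecified, so the split was a design choice.
Activity categories (work, commercial, social, personal care,
culture/religion/education, recreation, transportation, unassignable) are
taken as given input labels; free-text classification is out of scope.

## 3. Inclusion criteria and matched days

A GPS day is invalidated by a short registration period or by the device
being reported unworn for any reported out-of-home event of the day.
Reported days are invalidated for a participant with fewer than 2
reporting days for the indicator, and on contradiction: a TOH day with no
reported TOH but at least one reported AL, or an AL day with no ALs but
more than 30 reported TOH minutes. Comparisons use only participants with
at least 2 days where both sides are valid.

## 4. Agreement statistics

Two events *match* when their intersection is strictly positive; abutting
intervals do not match (intervals are half-open at 1-s resolution, which
makes this exact). Pooled recall is the share of reported events with a
GPS match; pooled precision the share of GPS events with a reported
match; F1 their harmonic mean. These are pooled over all events of all
participants, whereas IoU (intersection over union of the two merged
event timelines) and the intersection / REP-only / GPS-only duration
decomposition are computed per participant and then averaged — two
deliberately different aggregation scopes: pooling weights busy
participants by their event counts, while per-participant averaging gives
every individual equal weight in the durational summary. Match cardinalities (1:1, 1:n, 1:0) conserve the event total on
each side, and report-table percentages are rounded to integers.

Day-level differences are signed REP − GPS. Sample (n − 1) standard
deviations are used throughout. The Bland-Altman limits for multiple
observations per individual decompose the differences by one-way ANOVA
over participants: with group sizes $m_i$, $n$ participants,
$m_0 = (\sum m_i - \sum m_i^2 / \sum m_i)/(n-1)$,
$\hat\sigma^2_b = \max(0, (\mathrm{MSB}-\mathrm{MSW})/m_0)$ (negative
estimates truncated to zero), and the variance of a single difference is
$\hat\sigma^2_d = \hat\sigma^2_b + \mathrm{MSW}$, giving limits
$\bar d \pm 1.96\,\hat\sigma_d$. When every participant contributes one
difference this reduces exactly to the simple Bland-Altman limits.

The ICC is the one-way random-effects interrater coefficient treating each
participant-day as a unit rated twice (REP, GPS):
$(\mathrm{MSB}-\mathrm{MSW})/(\mathrm{MSB}+\mathrm{MSW})$, with a 95% CI
from the F distribution. The exact ICC formulation was not fixed by the
problem statement; one-way random effects was chosen because the
ANOVA-based estimator makes no rater-effect assumption between two sources
that are not interchangeable raters in the two-way sense. Negative
estimates are reported as-is. Spearman correlations are computed pooled
over all matched days and per participant (iCorr, summarised by mean and
SD; participants with under 3 days or zero variance are dropped with a
warning). Because a "one match" rate can be read either as exactly-one or
as at-least-one, the cardinality summary exposes both.

## 5. Sensitivity analysis

`agreement_curve()` re-runs event extraction and re-applies the inclusion
criteria identically at every grid value, yielding four series (F1 and
IoU for both indicators). `stepwise_optimize()` optimizes Tmax, then Tmin,
then Dmax, then re-confirms Tmin and Tmax, carrying each selection
forward. Threshold selection of this kind is often done by visual
inspection of the curves; an explicit scalar objective — the unweighted
mean of the four series, overridable by weights — replaces human judgement
so the procedure is reproducible. Ties break toward the smallest value, the most
conservative event definition. Default grids span the literature ranges:
Tmax ∈ {10, …, 420} min, Tmin ∈ {2, …, 15} min, Dmax ∈ {25, …, 500} m. A
grid value on which the objective is undefined (e.g. no GPS events
survive) is skipped with a warning.

## 6. The synthetic cohort

No raw cohort data are distributable, so the package ships a simulator
whose output is the test bed for every stage. Per participant-day it
draws a wake/sleep window, a Poisson number of outings, and for each
outing a Poisson number of stationary visits with log-normal durations
(truncated to 10–240 min) at places 300–2000 m from home and at least
300 m apart; travel is constant-speed straight-line movement in a locally
flat metric frame about the home (equivalent to great-circle travel at
city scale). Outings without visits are out-and-back walks. GPS fixes are
sampled at `gps_interval` (default 10 s; 1 s reproduces 1-Hz phone
logging, 30–60 s keeps test runtimes small) with isotropic Gaussian noise
(default 20 m outdoors and at home, where the device typically lies
charging; tripled at indoor visits to emulate indoor signal wander).
Indoor signal loss is bursty: a two-state process drops fixes with the
configured per-fix marginal probability (default 0.3) in runs of 30 fixes
on average, because real receivers lose signal in contiguous outages —
this is what makes `Tmax` interpolation consequential. Device-off windows
(log-normal length, default ~90 min, 30% of days) create long gaps and
mark overlapping reported outings as unworn; occasional short-registration
days (7%) exercise the 9-h rule. Diaries are derived from the truth by
omission (default 10%), Gaussian start/end shifts (5 min SD) and rounding
to 5-min clock times; spurious non-stationary entries (5% of days)
exercise the diary exclusion rules. All randomness sits behind one seed;
equal configurations give identical cohorts.

The generator emulates the statistical structure of a one-week cohort
study, not real-world detail: there are no transport modes, no
urban-canyon multipath structure, no multi-storey drift, no home
relocation, and diary errors are independent across events. Passing the
error-free limit (all error processes zero, thresholds compatible with
the generator) shows the pipeline is exact up to boundary discretisation
— each event boundary can be off by at most the geofence crossing time
plus one sampling interval — but says nothing about behaviour under error
processes the generator does not model.

## 7. Numerical conventions and degenerate inputs

- All event intervals are half-open `[start, end)` at 1-s resolution;
  interval algebra maps them to closed integer ranges internally, so
  abutting events never overlap and widths equal durations.
- Geofence and stop membership use an inclusive boundary (`distance ≤
  Dmax` is inside).
- Strict inequalities: diary deletion at duration ≤ 3 min; home
  replacement on strictly more buffered fixes; stop merging at distance
  < `Dmax` and gap < `Tmax`; matching at strictly positive overlap.
- Degenerate inputs: empty fix streams, all-noise anchor sets (invalid
  home with diagnostic), participants with zero event time (dropped from
  IoU means with a warning), zero denominators in precision/recall
  (reported missing with a warning), single-observation participants in
  the Bland-Altman reduction, and `msw = 0` in the ICC CI (degenerate
  interval [1, 1]) are all defined behaviours with tests.

## 8. Problem sizes

Test and reproduction runs use cohorts scaled to the method, chosen as
the package's own validation sizes: the error-free limit uses 5
participants × 7 days at 10-s sampling; oracle equivalence uses 100
random ≤200-fix days and 100 random event sets; the Bland-Altman
recovery uses 12 × 5 balanced differences over 1000 replicates; threshold
recovery uses ten 4 × 7 cohorts at 45-s sampling; the reproduction script
uses 8 × 7 at 30-s sampling.

## 9. Known limitations

- The stop scan is sequential (anchor-based); density-based global
  clustering, kernel home ranges and transport-mode inference are out of
  scope.
- Spatial correspondence between reported place names and GPS stop
  positions is not assessed — matching is purely temporal.
- The one-way ICC and the scalar optimization objective are declared
  choices among defensible alternatives; both are isolated behind small
  functions (`icc_interrater()`, the `weights` argument) so alternatives
  can be swapped in.
- Civil-time handling ignores DST transitions; studies spanning a clock
  change should pre-normalise timestamps.
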