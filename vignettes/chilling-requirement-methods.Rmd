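---
title: "Chilling-requirement models, bracket estimation and congruence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chilling-requirement models, bracket estimation and congruence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budchill)
```

## Scope

`budchill` covers the desk side of a chilling-requirement (CR) study on a
winter-dormant perennial: chill dose models over hourly temperature
records, interval estimation of the CR from dose–response experiments,
"reverse use" of the fitted CR to date fulfillment in other winters,
screening of temperature- and photoperiod-associated candidate genes
from an annotated FPKM matrix, 2^−ΔCt quantification of qPCR data, and a
lagged-profile congruence analysis linking expression shifts to the
fulfillment delay. Upstream molecular work (sequencing, assembly,
annotation, primer design) is consumed as finished tables and is out of
scope, as are alternative chill models (Utah negation, dynamic/chill
portions) and forcing-degree models; the weighting interface is the
extension point for those.

## Chill dose models

Both models weight each hour by a function of its air temperature and
sum the weights.

* **Chill hours.** `chill_hours()` weights an hour 1 iff its temperature
  lies in the inclusive band 0–7.2 °C. Endpoint inclusion matters for
  records that sit exactly on the bounds and is configurable
  (`inclusive_bounds`).
* **Chill units.** `chill_units()` weights an hour 1 below 0 °C, 0 above
  10 °C, and linearly in between: *w(T) = −0.0605·T + 1*. The weight is
  discontinuous at 10 °C by construction (0.395 just below, 0 above);
  it is still non-increasing everywhere, which the tests assert on a
  fine grid. Refrigerated storage without an hourly logger is handled by
  the closed form `constant_chill(T, hours, model)` with the storage
  midpoint temperature (default 2 °C for a 0–4 °C store); one week of
  such storage earns 168 CH or 168 × 0.879 = 147.672 CU.

**Window convention.** Accumulation windows are half-open `[start, end)`
on the hourly stamps. This makes totals additive over any partition of a
window and prevents double-counting the transfer instant when adjacent
windows share an endpoint (transfer clock times such as 9:00/10:00/11:00
become window boundaries).

**Missing hours.** Chill totals are sums, so silently skipping missing
hours biases them low. A gap inside an accumulation window is therefore
a hard error by default; `interpolate_gaps = TRUE` fills gaps of at most
`max_gap_hours` (default 3) by linear interpolation and reports the
filled count as `n_flagged`. Longer gaps always error.

**Start rule.** The accumulation start of a natural experiment is the
first date whose daily mean temperature stays strictly below the model's
upper effective temperature (7.2 °C for CH, 10 °C for CU) for
`persistence_days` consecutive days. The persistence window (default 3)
operationalizes a mean that has "steadily" passed the threshold: it
reproduces a unique start date on smooth winters and can be raised to
tolerate isolated warm spikes. Because clock conventions for published
start instants can be ambiguous (a "12.00 a.m." may mean midnight or
noon), accumulation functions always accept the start instant as
explicit input; `detect_start_date()` is a helper, never silently
applied.

**Rounding.** Accumulation is carried in full precision; only the
presentation layer rounds, with two-decimal half-up rounding
(`round_half_up()`), so 147.672 prints as 147.67 and 443.016 as 443.02.

## CR bracket estimation

A dose–response experiment yields per-treatment chill totals
(`treatment_accumulation()`: hourly integration for natural treatments,
the closed form for storage treatments, and 0 for a control transferred
before the start date) and a morphology table. Since no universally
accepted numeric adequacy criterion exists, adequacy is an explicit rule
set (`adequacy_rules()`), by default *final budbreak percentage ≥ 95 and
at least one opening flower per replicate mean*; the rules are attached
to every result so reports echo them.

The estimator (`estimate_cr()`, the package's central fit object)
brackets the CR between the largest inadequate dose (open endpoint: that
dose was observed to fail) and the smallest adequate dose (closed
endpoint: that dose was observed to suffice). With no failing treatment
the lower endpoint is 0, closed; with no adequate treatment the CR
exceeds the maximum applied chill and estimation errors rather than
guessing. Independent experiments combine by interval intersection
(`intersect_brackets()`), which propagates endpoint openness and returns
an explicitly empty bracket when the evidence is disjoint — as happens
for the published chill-unit intervals, a genuine disagreement the
package reports rather than reconciles. Where natural- and
artificial-experiment optima differ, the package reports per-experiment
optima and the intersection; it never blends them into a single figure.

Treatment ranking replaces per-index significance testing (out of scope)
with a documented composite score: per-index treatment means are
min–max scaled, lower-is-better indices (waiting times, abortion rates:
DEA, PAF, DFS, DFF) inverted, and the weighted mean taken. All-constant
indices are dropped with a warning; score ties rank the cheaper chill
dose first, so the "optimal" treatment is the first saturated dose.

## Reverse use: fulfillment dates and delay

Given checkpoint accumulations for a winter (`checkpoint_series()`, or
`checkpoints_from_series()` from an hourly record), the fulfillment date
is the earliest checkpoint whose accumulated chill meets the CR; it is
monotone in the CR by construction. The delay between two winters is the
calendar-day difference of their fulfillment dates after aligning the
first checkpoints of the two winters' matching sampling calendars
(removing the whole years between them), reported also in whole weeks
(days/7, rounded — a 14-day checkpoint gap is two weeks).

## Expression screening and qPCR

* **Differential screen.** The retained set is
  `(max + c) / (min + c) ≥ fold` and `max ≥ min_peak` per gene across
  checkpoints, defaults fold = 4, min_peak = 1 FPKM, pseudocount
  c = 0.1 FPKM. A ratio criterion with pseudocount is scale-covariant
  and safe on zero rows; the thresholds are configuration surfaced in
  every report, not a claim about any particular published gene count.
* **Keyword classification.** Case-insensitive substring matching of
  configurable phrase lists over description + homolog name; the
  temperature list is screened first, so dual matches class as
  temperature with a `both` flag. Grouping by homolog name
  (`summarize_by_homolog()`) keeps the total equal to the gene-set size,
  with unnamed homologs pooled under "No Arabidopsis gene name".
* **Heatmap standardization.** Per-gene z-scores with the population
  (n-denominator) standard deviation, clipped to ±3 — the conventional
  symmetric heatmap scale; constant genes map to zero. The exact
  normalization of legacy heatmap software being undocumented, this
  choice is declared rather than inferred.
* **qPCR.** `2^−ΔCt` against the in-sample reference gene; no calibrator
  sample is defined, so no ΔΔCt. Technical triplicates are averaged
  within each biological replicate (target and reference alike), each
  biological replicate is quantified against its own reference mean, and
  biological replicates summarized as mean ± SD. Triplicates whose Ct
  range exceeds 0.5 cycles are flagged but never dropped silently.

## Congruence analysis

Six-point profiles are very short, so the lag machinery is deliberately
minimal: Pearson correlation over the overlapping checkpoints at every
whole-checkpoint lag in ±`max_lag` (default 2), with at least three
overlapping points enforced, constant overlaps skipped, and ties broken
toward the smaller |lag| then the negative lag. Classification into the
three congruence types is by declared thresholds: `shifted_similar`
requires |lag| ≥ 1, r_best ≥ 0.8 and an improvement of ≥ 0.2 over the
lag-0 correlation (the gain term keeps smooth monotone profiles, which
correlate highly at every lag, from being called shifted);
`partially_similar` requires max(r) ≥ 0.5; everything else is
`dissimilar`. A gene is **CR-congruent** when it is `shifted_similar`
and its shift, converted to days by the median checkpoint spacing,
matches the fulfillment delay to within one checkpoint interval — a
shift of a month against a two-week delay fails this. Irregular real
sampling calendars (14–27 day gaps) are summarized by their median
spacing for this conversion.

## Synthetic data: what it emulates and what it does not

The generators make every stage testable without downloads and define
the package's validation conditions.

* `simulate_winter()`: annual cosine (minimum at mid-January) + diurnal
  cosine (minimum pre-dawn) + stationary AR(1) hourly noise + a uniform
  `warm_offset`. Defaults (`seasonal_mean` 4 °C at the winter minimum,
  amplitude 10 °C, diurnal ±4 °C, rho 0.7, sd 1.5 °C) give a
  subtropical east-China winter shape: daily means fall below 10 °C in
  early–mid November and below 7.2 °C around the turn of December, so
  start-date detection, daily means and both chill models are all
  non-trivial. It does not emulate weather fronts, multi-day warm
  spells, or recorder dropouts (gaps are injected explicitly in tests).
* `simulate_morphology()`: each index responds to chill through a
  logistic centred on the planted requirement C\*,
  `baseline + (saturation − baseline)·logistic(steepness·(chill − C*))`,
  mirrored for lower-is-better indices, with additive replicate noise
  (defaults: ~2 percentage points on budbreak percentages, 0.3 flowers —
  typical of 3-replicate scoring). Note the default adequacy rule
  (FBP ≥ 95 of a 20→100 logistic) is met at C\* + ln(15)/steepness, not
  at C\* itself; noiseless property tests therefore assert containment
  of that effective threshold, while the weekly storage grid (0–840 CH
  in 168-CH steps, the design of the storage experiment) keeps both C\*
  and the effective threshold inside the same bracket step, so the
  stochastic recovery checks assert containment of C\* directly.
* `simulate_expression_pair()`: CR-tracking genes carry a Gaussian bump
  (width 1 checkpoint, matching an active period of about two sampling
  dates) centred on each winter's fulfillment checkpoint, so the planted
  lag is the checkpoint difference; late-photoperiod genes rise
  monotonically toward the last checkpoint in both winters (the
  specificity challenge: ramps correlate highly at every lag);
  fluctuating genes are noise. Profile noise is additive with sd in
  units of the profile's own spread; Ct values are derived as reference
  Ct − log2(relative abundance) with cycle-scale noise (sd 0.15), so
  qPCR aggregation is exercised on realistic numbers. Real RNA-Seq
  features that are *not* emulated: library-size effects, count
  overdispersion, unreplicated-design artifacts — passing recovery tests
  shows the machinery is correct, not that six unreplicated libraries
  identify genes reliably.

All generators are pure functions of their configuration including the
seed, and restore the caller's RNG state.

## Validation conditions and problem sizes

The test suite runs the worked examples exactly (storage constants,
bracket algebra, key-point fulfillment, homolog totals) and four
stochastic recovery checks: closed-form/hourly equivalence on constant
series (tolerance 1e−9); CR-bracket containment of a planted 600-CH
requirement over 200 seeded weekly-storage scenarios with the default
morphology noise (≥ 95 % required); planted profile-lag recovery over
500 trials at noise sd 0.2 (≥ 90 %); and 200 end-to-end paired-winter
runs (a warmer twin winter, `warm_offset` 1 °C, which typically delays
fulfillment by one biweekly checkpoint) requiring ≥ 90 % sensitivity and
specificity for flagging CR-tracking genes, where a gene counts as a
detectable positive only when its winter pair realizes a shift of at
least one checkpoint — a zero-shift pair has no delay for a gene to be
congruent with. These sizes keep the whole suite under a minute on one
CPU while estimating the rates to a few percent.

## Known limitations

* Six checkpoints bound the lag search to ±2 and make correlation
  estimates coarse; the congruence typing is a screening heuristic, not
  a test with error control.
* The CR bracket is only as fine as the treatment grid; it never
  interpolates within a step.
* The chill models carry no negation of chill by warm hours; in
  climates with strong mid-winter warm spells both models overcount
  relative to Utah-family models.
* Adequacy, screening and congruence thresholds are declared
  configuration; conclusions should be checked for sensitivity to them.
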