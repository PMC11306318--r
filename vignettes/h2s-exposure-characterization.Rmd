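---
title: "Characterizing sporadic H2S exposure: the index, the cohort pipeline and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing sporadic H2S exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2sindex)
```

## Why a peak-sensitive index

Hydrogen sulfide produces both chronic effects, for which cumulative
dose matters, and acute effects triggered by short excursions above
threshold levels. A gas whose exposure profile is "almost always zero,
occasionally a one-to-four-minute peak of 2–30 ppm" defeats the two
standard summaries: the 8-h time-weighted average (TWA) averages the
peaks away (over a 480-min shift a single 15-s reading of 1.6 ppm
contributes 0.00083 ppm), and a bare ceiling-exceedance flag throws
away both the number and the magnitude of peaks. The daily index
implemented in `compute_index()` combines seven terms — peak counts in
four concentration bands, time spent in two duration bands, and the
daily maximum — so that a day's score grows with how often, how high
and how long a worker was exposed.

All band logic runs on the integer deci-ppm grid (`0.1 ppm`
resolution), with bands implemented as half-open intervals with edges
at 0.05/1.05/5.05/10.05 ppm internally. This makes membership of
grid values unambiguous under floating point, while reports use the
conventional printed edges (0.1–1.0, 1.1–5.0, 5.1–10.0, >10).
Ceiling-value exceedance is strict: a maximum of exactly 10.0 ppm does
not exceed.

### Excursions

An excursion ("peak") is a maximal run of consecutive readings at or
above the 0.1-ppm detection floor; a single qualifying reading is one
excursion; a dip within a band (12 → 6 → 12 ppm) does not create a
second peak — only a drop below the floor, or a gap in the reading
grid (unrecorded time), ends a run. This is the simplest rule
consistent with counting "peaks in a band", and it makes excursion
counts invariant to concatenating logs at their true timestamps.

### Two peak-count conventions

Whether an excursion peaking at 7 ppm counts once (in its top band) or
three times (every band it crosses) is genuinely open. The package
keeps both:

* **cumulative** (default): the single-reading log at the 1.6-ppm LOD
  scores 0.1 + 0.025 + 1 + 1.6 = 2.725, and 2.725/√2 = 1.927 — the
  imputation constant in use for the alarm-detector datasets, which is
  why cumulative is the default;
* **max_band**: the same log scores 2.625 (constant 1.856). The
  lowest possible index for a ceiling-exceeding day is 21.35 under
  max_band and 27.45 under cumulative; published figure annotations
  near 21.4 are consistent with the former, so neither convention
  dominates all published numbers. The convention used is always
  recorded in output metadata, and every index-bearing function takes
  a `mode` argument.

### TWA, censoring and imputation

`compute_twa()` divides the concentration-time sum by a fixed 480-min
reference shift regardless of log span, matching the convention of the
instruments' own 8-h display. The TWA of an empty log is `NA`, not 0.
A measured day with no reading at or above the LOD is left-censored:
exposure below the floor is unobservable, so its index cannot honestly
be 0. `impute_censored()` assigns such days the lowest index value at
the LOD divided by √2 — the classical LOD/√2 device transported to the
index scale. Real-zero days (sick leave, holidays, education, union
work, compensation days, identified from the work-log roster) are the
one class of days whose zero is believed, so they keep their value in
descriptives and are excluded from the model frame. The imputation is
idempotent and touches only censored measured days.

At a LOD of 0.1 ppm the constant is interval-dependent
(0.2 + 0.1·t/60 for interval t seconds, cumulative); since the
expert-campaign instruments' logging interval is not part of the
device exports we handle, the package computes the constant from the
interval it is given rather than hard-coding a value for that
instrument class.

## Logbook cleaning

Logbooks written by workers during the shift carry systematic quirks
the pipeline codifies rather than fixes silently:

* *End times in the duration field.* A raw value is reinterpreted as an
  end-of-task clock time when, read as minutes, it would push the task
  past 24:00, or when it parses as a clock time later than the start
  (threshold 720 min, configurable). Every decision is recorded
  per task (`duration_rule`), so audits can diff the corrections;
  irrecoverable values stay `NA` and flagged.
* *Multi-day entries* are split to one record per date.
* *Unknown task categories* are kept verbatim and flagged — category
  vocabularies drift between worker groups, so the controlled
  vocabulary ships as editable configuration.
* *Flushing* is an ordered factor none < some < much, absence of
  mention meaning none (most workday records carry no flushing entry).
* *Weekend/holiday all-zero measurement days* are dropped unless the
  person also logged activity that day; a day with any reading at or
  above the LOD is never dropped. The holiday calendar is an input,
  not a built-in table.

Day classification (`classify_days()`) is an exhaustive partition:
measured, else real-zero when the roster shows an absence-type reason,
else missing.

## The mixed model

`fit_varcomp()` fits index ~ group + season + (1 | worker) by REML via
`lme4`, by default on log(index): imputed datasets are strictly
positive and heavily right-skewed, and the published-style cell means
with asymmetric intervals arise naturally from back-transforming a
log-scale Wald CI (`predict_cell_mean()`; back-transformed point
estimates are geometric means — the simplest defensible default, and
the choice is recorded in the result object). Variance decomposes into
a between-worker component (random-intercept variance) and a
within-worker component (residual); the within-worker share is the
headline quantity for an exposure driven by task-to-task variation
rather than stable worker differences. Model comparison uses
−2 logLik from an ML refit, since REML likelihoods are not comparable
across fixed-effect structures; a decrease means a better fit.

The split-half robustness device (`robustness_split()`) bipartitions
the positive measurements with activity data by per-point fair coin,
redrawing until each half holds 50% ± 2.5% of all points and
simultaneously 50% ± 3.5% within every similar-exposure group —
rejection sampling is faithful to "iterate random draws until the
tolerances hold" and trivially verifiable (`check_split()` is an
independent checker, and splits are reproducible from their seed). A
group of odd size n is infeasible when 0.5/n exceeds the per-group
tolerance (so odd groups below 15 points fail fast with the group
named).

## The synthetic cohort

The generator (`simulate_latent_cohort()`) produces the *latent*
exposure process; strategy operators then observe it. Defaults encode
the study conditions the pipeline targets:

* 60 workers in four similar-exposure groups (24 wastewater network,
  15 treatment plant, 6 pumping stations, 15 water distribution
  network) over a 34-week window containing three 2-week campaign
  periods (late February, early June, early September) — about 10⁴
  scheduled person-workdays;
* day statuses: 23% real zero, 11% missing, independently per day (no
  dependence structure is claimed for missingness);
* exposure is sporadic: a working day carries at least one excursion
  with probability 0.50–0.65 by group (campaign-condition rates at
  which roughly 60% of measured days show a detect at the 1.6-ppm
  floor); most exposed days have a single excursion
  (1 + Poisson(0.15), capped at 8);
* excursion peaks are log-normal with meanlog log(6) + 0.45² and
  sdlog 0.45 — mode 6 ppm, inside the 5–8 ppm mode band seen in
  daily-maximum histograms of such data — plus a rare
  "confined-space incident" mixture component (probability 0.005,
  meanlog log 30) so that readings above the 100-ppm instrument
  ceiling occur a handful of times per 10⁴ days rather than never;
  a worker-level shift on meanlog (sd 0.4) creates between-worker
  variance, deliberately small relative to within-worker variance;
* excursion lengths are 1 + Geometric(0.55) readings truncated at 15
  (just under 4 min at the 15-s cadence), placed in non-overlapping
  slots of a 1920-reading 8-h shift, as block pulses;
* manhole-entry counts are Poisson with per-group daily rates set so
  water-network workers enter about 18× as often per person as
  wastewater-network workers; logbook context exists for 81% of
  workdays.

Block pulses (every reading of an excursion equals its peak) are a
deliberate simplification: they make the vectorized strategy operator
provably identical to materializing each day's `gaslog` and running
the reading-level pipeline (the equivalence is asserted in the tests),
at the cost of not exercising within-excursion shape. Nothing
downstream depends on that shape except the split of a single
excursion's duration between the two duration bands.

The strategy operators only select, censor (below-LOD readings record
as 0, values above 100 clip with an overload flag) and truncate:

* **A (expert campaign)**: 93 person-days drawn with a targeting bias
  (default 0.8) toward days that in truth carry exposure, emulating
  workers steering measurement days; floor 0.1 ppm.
* **B (routine self-assessed)**: detectors dock weekly (Fridays); the
  16-h wraparound preserves full readings only for the dock day and
  the workday before; other transferred days appear as all-zero logs
  unless the separate alarm slot kept the day's maximum as a single
  datapoint (alarm set point 10 ppm; docking after an alarm retains
  the full day with probability 0.9). A worker who never docks
  contributes nothing.
* **C (intensive self-assessed)**: every non-missing workday of the
  campaign periods is observed, with logbooks attached at the
  reporting rate.

What passing tests on this simulator do show: the pipeline's
arithmetic is exact at the reading level; classification stays a
partition; the strategy comparison reproduces the qualitative field
pattern (daily collection detects roughly twice the exposed-day
fraction of routine docking; expert targeting enriches very high
days). What they do not show: that real H₂S exposure follows
log-normal block pulses with Poisson placement (within-day temporal
clustering is unknown and not modelled), that real missingness is
independent, or that the field datasets' model estimates are
recovered — those depend on the deposited measurement data, which the
simulator deliberately does not imitate beyond the printed
distributional anchors.

## Numerical and design choices

* Deci-ppm integer grid for all band/LOD/ceiling comparisons; strict
  inequalities at the 10-ppm ceiling and the 100-ppm overload edge.
* Zero-skip transfer gaps up to 4 h are refilled with explicit zeros
  (the documented device behaviour); longer gaps split the log — a
  shift break is not distinguishable from a device being off, and
  excursions never bridge unrecorded time.
* Reported values round half away from zero at printed precision
  (`round_half_up()`); base R's round-half-even does not reproduce
  printed study-workday totals.
* Overlapping logs for the same person-day resolve per timestamp by
  the maximum.
* Study-duration workdays use 220 workdays/year/person; the study
  frame of scheduled person-workdays is an explicit input where it is
  not measurement-days × persons.
* Cross-dataset detection uses the common 1.6-ppm floor even for
  instruments resolving to 0.1 ppm, keeping strategies comparable.
* The index–TWA fits are least squares of log10(index) on log10(TWA),
  per ceiling stratum and pooled; the fit space is a package choice
  recorded in output metadata.
* Seeds are mandatory wherever randomness enters (splits, simulation,
  strategy application); all outputs carry `provenance.json`.

## Problem sizes

The shipped analysis scripts and the test suite run the full pipeline
on the ~10⁴-person-day default cohort (seconds on one CPU, thanks to
the vectorized strategy path) and use 200-replicate simulations at 60
workers × 15 days for parameter-recovery checks of the mixed model —
sizes chosen to give stable Monte Carlo margins while keeping a full
run interactive.

## Known limitations

* The B-strategy retention model (fixed Friday docking, 2-day
  wraparound window) is a stylized stand-in for real docking
  compliance, which is irregular.
* No sensor drift, calibration cycles, bump-check failures or CO
  cross-sensitivity are modelled; no real-time alarm logic.
* Imputation by a fixed constant is honest only while censored days
  are a modest fraction of the model frame; with 30–80% censoring no
  fixed-value (or simple distributional) imputation represents
  high-end risk well — the package reports censoring fractions so the
  analyst can see when the model frame is dominated by the constant.
* Free-text logbook comments are not interpreted; conflicting
  duplicate entries resolve last-write-wins with a warning.
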