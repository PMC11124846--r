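---
title: "Classifying grazing-cattle behavior from collar accelerometers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying grazing-cattle behavior from collar accelerometers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Collar-mounted tri-axial accelerometers record the acceleration of a grazing
animal's neck at tens of hertz. Because posture and movement leave
characteristic marks on those three channels, a classifier trained on
time-windowed summary statistics of the signal can recover the animal's
behavioral state — grazing, walking, resting, ruminating, grooming — second
by second, far beyond what human observation can cover. `grazeclass`
implements that pipeline end to end: a synthetic signal generator for
testing, ingestion and cleaning of observed-behavior records, windowed
feature extraction, ensemble-tree classification, and the two experiment
drivers that answer the practical design questions — how long a smoothing
window to use, and how much labeled observation time is actually needed.

## Axis convention and the signal model

The collar frame is **+X forward, +Y right, +Z down**. Accelerometers
measure gravity plus movement, in units of g, so a standing, idle animal
reads approximately (0, 0, 1) g. The literature is not consistent about this
convention, so it is worth stating plainly: here **+1 g appears on whichever
axis points down**.

The synthetic generator models each behavior's signature as

* a **gravity vector rotated by a pitch angle about the Y-axis** — 0° for
  resting/ruminating/walking (gravity on +Z), 90° for grazing, whose
  head-down posture transfers the gravity component from the Z-axis onto the
  X-axis (this is the single most diagnostic feature of grazing),
  30° for grooming;
* a **locomotor/chewing sinusoid**: a ~2 Hz gait oscillation for walking
  (amplitude 0.30 g), a ~1 Hz chewing rhythm for ruminating (0.05 g) and
  grazing (0.10 g);
* **Gaussian dynamic noise** per axis: 0.05 g for the quiescent behaviors,
  0.15 g for walking, 0.25 g for grazing (biting and tearing forage is
  energetic), 0.30 g broadband for grooming, which in real data is a mixed,
  heterogeneous signal.

No published amplitude values exist for these signatures; the defaults were
chosen once to reproduce the qualitative separations seen in real collar
data — grazing separable mainly by static X, walking by periodicity and
VeDBA, grooming broadband — and are deliberately not tuned further. Bout
transitions are blended with a 0.5-s cosine ramp so that boundaries are not
artificially sharp.

### Bout schedules

Behavior sequences follow a semi-Markov model: bout durations are
exponential with per-behavior means (grazing 300 s, resting and ruminating
120 s, walking 30 s, grooming 15 s), and successive behaviors are drawn with
probability proportional to `target_share / mean_duration`, which makes the
long-run time shares converge to the targets. Default shares are resting
35.5%, grazing 33.5%, ruminating 21.5%, walking 9.4%, grooming 0.1% — the
composition reported for extensively grazed steers. Grooming's tiny share is
intentional: it makes the rare-class degradation that plagues real
deployments reproducible in tests. The exponential law is the simplest model
consistent with "bouts"; it ignores diurnal rhythm and behavioral
autocorrelation beyond the bout level, so synthetic results say nothing
about time-of-day structure.

### What the generator does not emulate

Real collar data contain collar spin, time drift, transitional postures,
individual variation in gait frequency, and observer labeling error. The
first two are available as explicit corruptions (`corrupt_signal()`) for
robustness checks, but the default study conditions are clean. Passing
classification benchmarks on synthetic data therefore demonstrates that the
pipeline is correct and that the published effect directions (window-size
plateau, data-reduction asymptote, rare-class fragility) follow from the
signal structure — not that a field deployment will reach the same absolute
accuracy.

## Ingestion and cleaning

Observed behavior arrives from two sources: a continuous 1-s in-pasture
observation stream, and 15-s collar-video clips recorded hourly. Collar-video
clips in which the animal switches behavior are removed whole
(`filter_video_clips()`), since a mixed clip cannot be matched cleanly to
the accelerometer trace. Epochs are integer UTC seconds; bouts are half-open
intervals `[start, end)` so boundary seconds are never double-labeled.

Manual signal verification (checking that a labeled trace "looks like" its
behavior) is inherently irreproducible, so it is replaced by configurable
rule-based flags: grazing epochs whose 10-s mean static X falls below 0.3 g,
and resting epochs whose 10-s mean VeDBA exceeds 0.2 g, are flagged for
exclusion. Both thresholds are exposed in `mismatch_rules()`.

GPS fixes (15-min interval) attach to bouts by nearest time against the bout
midpoint; ties break toward the earlier fix — an arbitrary but fixed and
documented rule.

## Feature extraction

Static acceleration is a centered 2-s running mean per axis (a biologging
convention; the span is configurable), shrinking to the available samples at
the edges; dynamic acceleration is raw minus static, so the decomposition is
exact by construction. From the dynamic channels,
`ODBA = |dx| + |dy| + |dz|` and `VeDBA = sqrt(dx^2 + dy^2 + dz^2)`; the
Cauchy–Schwarz bounds `VeDBA <= ODBA <= sqrt(3) * VeDBA` hold per sample and
are asserted in the test suite.

At every 1-s epoch, for a smoothing window of `w` seconds, the feature
vector holds: the raw-axis snapshot at the epoch, windowed
mean/median/sd/min/max per axis, the dynamic-axis snapshot, instantaneous
ODBA and VeDBA, and windowed statistics of both — 33 features, or 51 with
magnetometry (raw + five statistics for each of three axes). Numerical
choices, each pinned by an oracle test:

* **sd is the population standard deviation** (divisor N);
* **windows are trailing by default** (the window ends at the epoch),
  matching causal real-time use; centered alignment is available;
* **partial edge windows are dropped**, not shrunk, so every epoch's
  features are computed from exactly `w × 40` samples and are comparable;
* windowed statistics are computed from per-second aggregates combined
  across the window (medians from the raw samples), and the tests verify
  exact equality against a naive per-window recomputation.

Zero-phase Butterworth low/high-pass channels (order 2, 0.3 Hz cutoff by
default; neither value is prescribed anywhere, both are configurable) are
available but off by default, since their role in the published analyses is
illustrative. The filter applies odd-reflection padding before
forward–backward filtering; the effective gain is the squared one-pass
magnitude response, which the tests check against the analytic transfer
function.

## Classification and metrics

The classifier is a random forest (via `ranger`): 500 trees, `floor(sqrt(p))`
candidate features per split, unlimited depth, single-threaded for exact
reproducibility. Key columns (animal, epoch, window, label, source) are
excluded from the predictors automatically, and the ordered feature schema
is stored with the model and enforced at prediction time.

The 70/30 train/test split is stratified by (animal, behavior) with the
train share within one row of 70% per stratum. A purely random per-epoch
split — apparently the published procedure — lets temporally adjacent (and
hence correlated) epochs straddle the train/test boundary, which inflates
held-out accuracy for any smoothing window longer than 1 s; this is the
main reason absolute accuracies in this setting approach 1. The stratified
per-epoch split is the default because it mirrors that procedure;
bout-level blocking would be the conservative alternative and is the main
known limitation to flag when transferring accuracy claims to new animals.

From the confusion matrix (rows = observed, columns = predicted):
accuracy = trace/total; per class, sensitivity = TP/(TP+FN),
specificity = TN/(TN+FP), precision = TP/(TP+FP). Metrics with zero
denominators are reported as `NA` — never coerced to zero — with a warning;
this matters precisely for rare classes like grooming, which can vanish from
a test set. Micro-accuracy equals the prevalence-weighted mean of per-class
sensitivities; the suite asserts this identity on random matrices, and
cross-checks all metrics against an independent reference implementation.

## Experiments

**Window sweep.** For each window size in {1, 2, 5, 10, 15, 20, 30, 60} s,
features are extracted once and the split/train/evaluate cycle is replicated
over 10 seeds. The plateau of a curve is the smallest window whose mean
metric is within 1% (relative) of the curve's maximum — the published
"optimal window" has no stated criterion, so this one is defined explicitly.

**Data reduction.** `structured_subsample()` retains `round(p × n)` rows in
every (animal, behavior) cell — preserving each animal's behavior
composition — and the bootstrap repeats subsample → split → train → evaluate
`B` times per retention proportion. Both the standard deviation and the
standard error of the replicate distribution are stored (reports of such
curves use sometimes one, sometimes the other; plots here default to sd).
Desk-scale defaults are a {1, 5, 10, 25, 50, 75, 100}% grid with B = 25;
the full 1–100% × B = 100 design is a parameter change.

**Source comparison.** Per-source models are trained on subsets size-matched
to the smaller source's per-behavior counts, so a difference in metric
reflects label quality and coverage, not sample size.

### Problem sizes and replication defaults

The package's study-scale defaults are 8 animals × 2 500 s, about 20 000
labeled 1-s epochs — the same order as the published corpus (28 244 s) — with
10 replicate splits per sweep point and B = 25 bootstrap replicates.
Experiment forests default to 150 trees: out-of-bag error on these feature
sets plateaus well below 100 trees, and the replicate-to-replicate spread is
dominated by the split, not forest size. `train_classifier()` itself keeps
the conventional 500-tree default. All of these are arguments, not
constants.

On these defaults the synthetic study reproduces the published effect
structure: full-ethogram accuracy ≈ 0.99 at the 10-s window, the accuracy
plateau reached by 10 s (and no later for the grazing-binary task), activity
grouping above 95% accuracy from a 25% subsample, and grooming collapsing
under data reduction while grazing is barely affected.

## Degenerate inputs and edge rules

* Windows longer than the frame yield an empty table with a warning;
  unusable sweep points are skipped with a warning, never silently dropped.
* Strata with fewer than two rows fall back to a pooled split (warning).
* A subsample or retention proportion that leaves a single class skips that
  point with a warning rather than fitting a degenerate model.
* Recording gaps longer than two sample intervals split a signal file into
  separate frames; duplicate timestamps are an error naming the row.
* Percentage shares are rounded half away from zero at one decimal, the
  convention of the published summaries (base R's `round()` is banker's
  rounding and would disagree at exact halves).

## Known limitations

Synthetic signatures are stationary within a bout; real behaviors drift.
The per-epoch split's leakage caveat above applies to every absolute
accuracy quoted here. Magnetometer simulation is a heading random walk with
a fixed-inclination field — adequate for pipeline testing, not for
geomagnetic work. The significance tests quoted in some summaries of this
study design have no described procedure and are deliberately not
implemented.
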