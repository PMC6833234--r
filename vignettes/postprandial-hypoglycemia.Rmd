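---
title: "Predicting postprandial hypoglycemia from CGM traces and meal announcements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting postprandial hypoglycemia from CGM traces and meal announcements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pphypo)
```

## The problem

Around mealtimes, glucose in people with insulin-treated diabetes moves fast:
carbohydrate absorption pushes it up while bolus insulin — sometimes injected
late, sometimes still active from a previous meal ("insulin on board") —
pushes it down. Hypoglycemia in this window (a sensor reading below
70 mg/dL, 3.9 mmol/L) is harder to predict than nocturnal hypoglycemia
precisely because of these fluctuations, yet a timely warning lets a patient
eat carbohydrate or lets a closed-loop system cut insulin.

`pphypo` implements a deliberately light-weight approach: from a continuous
glucose monitoring (CGM) trace sampled every 5 minutes and nothing more than
user meal announcements, predict whether glucose will be below 70 mg/dL
30 minutes ahead, at every 5-minute step from 5 minutes to 3.5 hours after
each meal.

## The model

### Features and labels

For meal $j$ of series $i$, with the post-meal window indexed
$t = 0, 1, \dots, 42$ (5 minutes per step, $t = 0$ at the meal), the three
features at prediction step $t$ are:

* **CGM** — the glucose at step $t$ itself, in mg/dL;
* **RIG**, the rate of increase in glucose — the rise from the meal-time
  value to the running post-meal peak, divided by the time from meal to
  peak:
  $\mathrm{RIG}_t = (\mathrm{CGM}_{\mathrm{peak}(t)} - \mathrm{CGM}_0) /
  (5\,\mathrm{peak}(t))$, where $\mathrm{peak}(t)$ is the smallest index of
  the maximum over steps $0..t$. Once the true peak has passed, the running
  maximum freezes, so RIG stops changing — it summarizes how steeply the
  meal drove glucose up. When there is no post-meal rise
  ($\mathrm{peak}(t)=0$), RIG is 0 by convention, which also avoids a zero
  denominator;
* **GRC**, the glucose rate of change — the 5-minute first difference
  $(\mathrm{CGM}_t - \mathrm{CGM}_{t-1})/5$, the near-instantaneous trend at
  prediction time.

The label at step $t$ is 1 iff $\mathrm{CGM}_{t+6} < 70$ mg/dL — a 30-minute
prediction horizon, the standard compromise between warning time and
accuracy. Samples are emitted for $t = 1..42$ whenever every point they need
is present (steps $0..t$ for the running peak, $t+6$ for the label); anything
else is skipped and counted, never imputed beyond the gap rule below.
Features are min-max normalized with extrema learned on the training folds
only.

### Preprocessing

* **Gap filling.** Runs of 1–2 consecutive missing readings are filled by a
  natural cubic spline fitted on all present points of the series; runs of 3
  or more are left missing. The global fit (rather than a local one around
  each gap) uses all available shape information and is idempotent; with at
  most two points missing the two dialects differ negligibly on 5-min CGM
  data.
* **Meal announcements.** In the data this package emulates, meal times are
  pre-meal calibration finger-sticks, so some announcements are nocturnal
  and some are near-duplicates. Announcements in the nocturnal interval
  [23:00, 07:00) are removed — half-open, so an 07:00 announcement survives.
  Then, scanning forward, whenever two surviving announcements are strictly
  less than 2 h apart the earlier is dropped, transitively: of any chain of
  announcements pairwise closer than 2 h only the last survives. An exactly
  2-hour spacing does not merge.
* **Windows.** Post-meal windows may overlap when meals are 2–3.5 h apart;
  each meal harvests all its own points. Windows truncate at the series end;
  steps that would need out-of-range points simply emit no sample.

### Cost-sensitive training

Hypoglycemia labels are rare (roughly one positive per 8–16 negatives), so
all five classifier families — random forest (RF), linear and RBF support
vector machines (SVM-LN, SVM-RBF), K-nearest neighbors (KNN) and logistic
regression (LR) — are trained cost-sensitively. The false-negative cost is
the exact negative:positive count ratio of the training folds, the
false-positive cost is 1, correct decisions cost 0. The cost enters as case
weights (RF), class weights (SVMs), observation weights (ridge LR) and a
multiplier on positive neighbor votes (KNN: the score is
$c\,n_+ / (c\,n_+ + n_-)$ over the $k$ neighbors, so the 0.5 cut is the
cost-weighted majority).

Validation is 5-fold **cross-subject**: patients, not series, are shuffled
and dealt round-robin into folds, so a patient contributing two series never
appears on both sides of a split. Hyperparameters are chosen by grid search
with subject-grouped 3-fold inner validation on the training folds,
minimizing the cost-weighted misclassification loss
$(c_{FN}\,FN + FP)/n$; ties break in declared grid order. The inner split is
subject-grouped for consistency with the outer design (grouping only on
series would leak dual-series patients).

Every model exposes a score in [0, 1]; the hard label is score ≥ 0.5.
The SVM score is the logistic transform of the decision value — a monotone
map whose 0.5 cut coincides with the class-weighted decision boundary, so
hard labels and AUC are unaffected by skipping Platt recalibration.
Thresholding affects only the confusion-matrix metrics; AUC is
threshold-free.

### Sample metrics and the event/alarm calculus

Sample-level performance uses sensitivity, specificity, precision, F1 and
the AUC of the ROC integrated by the trapezoidal rule (equal to the
rank statistic, ties ½). Ratios with empty denominators are reported as
`NA`, never 0, and are omitted from cross-fold averages.

Clinically, what matters is whether *events* are alarmed in time:

* A **hypoglycemic event** is a maximal run of ≥ 2 consecutive readings
  < 70 mg/dL; runs separated by ≤ 10 min merge. Events are kept when they
  start 5 min–4 h after a meal (start-exclusive, end-inclusive), assigned to
  the latest such meal, flagged *severe* when any reading is < 54 mg/dL
  (3.0 mmol/L), and flagged *excluded* when they start within 10 min of the
  meal — too early for the two prediction steps an alarm needs, so they are
  counted but not scored as alarmed or missed.
* An **alarm** is a maximal run of ≥ 2 consecutive positive predictions,
  stamped at its first step; runs wholly inside an ongoing event are not
  alarms.
* An event is **true-alarmed** if an alarm fires in the 60 min before its
  start; the earliest such alarm sets the detection time
  DT = start − alarm ∈ (0, 60]. An alarm preceding no event start within
  60 min is a false alarm; FAR = FP_e / (TP_e + FP_e). A false alarm is
  *near-hypo-related* when ≥ 2 consecutive readings ≤ 80 mg/dL (4.4 mmol/L)
  start within the hour after it.

Boundary choices the definitions leave open were fixed once: "more than two
consecutive" is read as ≥ 2 (consistent with its two-time-step gloss), a gap
of exactly 10 min merges, an event starting exactly 2 h after its meal's
announcement still belongs to it, and one unmatched alarm run counts one
false event regardless of its length. Per-fold DT and FAR are averaged
within folds first, then summarized as mean (SD) across folds.

## The synthetic cohort generator

The clinical data this method was designed for are not redistributable, so
the package ships a generator that emulates their structure: 5-min sampling
over 3 days, three daytime meals per day near 08:00/13:00/19:00 (±15 min),
nocturnal and duplicate announcements that the preprocessing must remove,
~1% missing points, and four postprandial archetypes — no peak, low peak
then fall, steep peak then rapid fall, and an insulin-on-board fall with no
peak.

Each meal response is a gamma-shaped rise minus a saturating insulin drop,

$$g(\tau) = \mathrm{base} + A\,\frac{\tau}{t_p} e^{1 - \tau/t_p}
          - D\,(1 - 2^{-\tau/h}),$$

floored at 40 mg/dL — the simplest 3-parameter form that realizes all four
archetypes (amplitude $A$, time-to-peak $t_p$, drop $D$ with half-life $h$).
In assembled series each meal's contribution wears off linearly between 270
and 330 min post-meal, so effects do not accumulate across a whole day;
overlapping contributions add. Sensor noise is AR(1) with coefficient 0.7
and stationary SD 5 mg/dL, mimicking retrospectively smoothed CGM traces;
values are rounded to 1 mg/dL.

Meals plant a hypoglycemic excursion with an archetype-specific probability
(0.15 / 0.20 / 0.35 / 0.40 — the steep-peak and insulin-on-board patterns
are the hypoglycemia-prone ones); planted meals size the drop to a nadir of
48–62 mg/dL, others stay above ~85 mg/dL. Ground truth is defined on the *noiseless* curve, so
any label noise is attributable to the sensor model, and the defaults are
calibrated so that 5–15% of all points (about 7% at the default seed) lie
below 70 mg/dL and negatives outnumber positives by well over 5:1,
mirroring the imbalance such cohorts show.

What the generator does **not** emulate: carbohydrate content and insulin
dosing (no physiological glucose–insulin ODE), circadian basal drift,
exercise, snacks, or sensor artifacts beyond AR(1) noise and dropout.
Passing tests on this cohort therefore demonstrate that the pipeline
recovers a planted postprandial signal under realistic sampling, imbalance
and noise — not clinical-grade performance on real patients.

## Problem sizes and defaults

The cohort-scale experiments in the tests and the acceptance script use 100
series (~300 subjects-days, ~38,000 samples), 5-fold cross-subject
validation, and one sensible hyperparameter setting per family (RF: 300
unlimited-depth trees; SVMs: C = 1, RBF γ = 1; KNN: k = 15; ridge LR:
C = 1): at this scale the experiments measure signal recovery, while the
grid-search machinery itself is exercised at small scale in its own tests.
The full default grids (`default_grids()`) remain available and
configurable for real analyses.

Numerical conventions worth knowing: the canonical unit is mg/dL throughout
(70 / 54 / 80 mg/dL for 3.9 / 3.0 / 4.4 mmol/L, conversion ×18.016), mmol/L
input is converted on read; spline-filled values are kept inside the sensor
range [20, 600]; the running-peak tie-break is the smallest index; grid
seeds fan out from a single experiment seed so cohort, folds and learners
are independently reproducible.

## Known limitations

* The event calculus follows the alarm definitions exactly; alternative
  conventions (per-step false positives, alarm snoozing) are out of scope.
* KNN distances are computed by chunked brute force — fine at this problem
  size, not for millions of samples.
* The generator's archetype parameters are qualitative emulations; only the
  cohort-level statistics above are calibrated.
* The default cohort is an easy sample-level problem: level plus slope
  30 minutes ahead of an excursion already separates the classes almost
  perfectly (AUC near 0.99 for every family), so the synthetic benchmark has
  no headroom to show the incremental value of RIG that clinical data can —
  the acceptance script's `rf_rig_auc_gain` is about zero here (slightly
  negative at the default seed).
* Significance testing across model families is intentionally not included;
  the per-fold tables are amenable to any standard test.
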