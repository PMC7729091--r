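---
title: "Methods: kinematic features and calibrated decision support for pediatric gait analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematic features and calibrated decision support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdss)
```

## The problem

Three-dimensional gait analysis in children with cerebral palsy produces,
per walking trial, a set of lower-limb joint-angle curves (pelvis, hip and
knee in three planes; ankle sagittal and transverse; foot progression),
each time-normalized to 101 samples over one gait cycle (t = 0..100% of the
cycle, initial contact at t = 0, stance ending at the ipsilateral foot-off).
Clinicians combine these curves with physical-examination measures (passive
range of motion, spasticity tests, muscle strength grades, bone alignment)
to identify musculoskeletal impairments and to formulate surgical
recommendations. `gaitdss` implements a decision-support pipeline for that
task: it reduces the curves to 49 binary, rule-based kinematic features,
joins them with the examination predictors, trains one probabilistic
classifier per outcome, calibrates the predicted probabilities, and reports
per-patient explanations.

The models imitate historical clinical labeling: they answer "given these
measurements, what would an experienced clinical team at this center have
concluded?", so their output is a calibrated probability rather than a hard
class.

## Curve representation and windows

A curve is exactly 101 angles in degrees. Clinical (Plug-in-Gait) sign
conventions are assumed throughout: anterior pelvic tilt, hip flexion, hip
adduction, hip internal rotation, knee flexion, ankle dorsiflexion and
internal foot progression are positive. The threshold rules of the feature
registry only read correctly under one convention, so the convention is
part of the data contract.

Windows are inclusive integer sets of t values. Stance is `0..floor(foot_off)`
and swing the remainder, so every sample belongs to exactly one phase.
Input series of any length are resampled by linear interpolation onto the
uniform 101-point grid (`resample_to_cycle`); linear interpolation is an
assumption (the originating systems do not state one) and is exact for
affine segments, idempotent on 101-point input, and endpoint-preserving.
No dynamic-time-warping alignment is applied before feature extraction;
features are defined on the common percent-of-cycle timebase.

## Reference bands: the four-step procedure

Each threshold feature compares a statistic of the patient's curve with a
normative band computed from typically developing children:

1. compute the statistic (for example the mean angle over t in [20, 45])
   on the curve under consideration;
2. compute the same statistic on each individual curve of the reference
   set (both sides of every typically developing trial are pooled; by
   default one trial per reference child);
3. take the mean and sample SD (n − 1 denominator) of the reference
   statistics;
4. the feature is present when the patient statistic falls beyond the
   stated multiple of the SD — strictly: "< 1 SD of typical mean" means
   `statistic < mean − 1·SD`, "> 2 SD" means `statistic > mean + 2·SD`,
   and boundary equality always counts as absent.

Left-right difference features ("mean difference between L&R > 1 SD of
typical difference") use bands of the signed left-minus-right mean
difference over reference trials, and fire when the patient difference
falls outside `mean ± 1·SD` in either direction, since elevation and
depression are two signs of one abnormality.

## The 49-feature registry

The registry covers pelvis (sagittal 6, coronal 2, transverse 3), hip
(6/4/3), knee sagittal (10), ankle (sagittal 11, transverse 1) and foot
progression (3). Features are conjunctions of atomic conditions over one
curve (plus, for the bilateral pelvic features, the contralateral curve):
band comparisons, comparisons against fixed angle constants (always
degrees), peak/pit existence and timing, least-squares slopes, bump
counts, and Pearson correlations against template curves. Notable
operational choices, configurable through `detector_control()`:

* **Peaks and pits.** A peak is a strict interior local maximum with
  prominence at least 20% of the full-cycle range of motion. Where a rule
  needs "the" peak (swing knee-flexion peak, hip-rotation peak timing), a
  qualifying local peak is preferred and the window's global maximum is the
  fallback — a clinician always identifies some peak. Cycle endpoints are
  never local extrema.
* **Double bump.** "Period is 2" is operationalized as a bump count of 2
  after a centered 5-sample moving average; the left/right-agreement clause
  compares the mean absolute side difference against 0.25 times the mean of
  the two sides' ROM (the rule's comparand is otherwise ambiguous).
* **Template correlations** (threshold 0.8) are taken as the maximum over a
  bank of templates: any matching exemplar suffices. The original in-house
  template curves are not public, so the defaults are constructed: two-cycle
  cosines at several phases for the double bump; the sign-flipped typical
  transverse pelvis mean curve for the reversed-rotation pattern; an
  analytic early-peak/declining/push-off shape for the short second rocker;
  and the typical foot-progression mean plus an external swing wave. All are
  overridable via `build_reference(..., templates = )`.
* **Unilateral inputs.** Features that need both sides return absent, with
  a warning, when only one side is supplied.

Custom detectors built from the same condition vocabulary can be registered
with `make_custom_detector()` and behave exactly like built-ins.

## Cohort assembly, filters and imputation

Each side is modeled separately, one record per session-side. Predictors
are the examination registry of the task (the surgery task uses a reduced
registry without strength grades) plus the 49 features. Two filters follow
the method's data rules: examination predictors must be collected for at
least 90% of the *children* (computed at the child level, not the record
level), and outcomes must have at least 100 positive records. Missing
examination values are imputed just before training — medians for
continuous measures, the most frequent category for categorical ones (ties
broken lexicographically) — and, critically, the imputation values are
fitted on the in-bag rows of each bootstrap resample and applied to its
out-of-bag rows, so validation never leaks into training. Imputed cells are
flagged and the flags survive into patient reports.

## Models, scoring and validation

Three candidates are raced per outcome: a standard random forest, a
stratified (balanced) random forest in which every tree trains on a
resample holding the minority-class count of *each* class (drawn with
replacement within class), and an elastic-net penalized logistic
regression. Class imbalance motivates both the stratified forest and the
evaluation metric.

The primary metric is the **weighted Brier score**
\[
  \mathrm{wB} = \frac{\sum_i w_i\,(\hat P_i - O_i)^2}{\sum_i w_i},
  \qquad w_i = \frac{1}{\text{freq of class } O_i},
\]
a proper scoring rule on probabilities in which minority-class errors carry
proportionally more weight. Normalizing by the weight sum (not by N) is
forced by an internal consistency requirement: a constant-0.5 predictor
must score 0.25 whether weighted or not, which holds under weight-sum
normalization only. Any admissible model must therefore beat 0.25.

Training and validation use 25 out-of-bag bootstrap resamples; models are
trained on each resample and validated on the records absent from it, and
the out-of-bag predictions are pooled across resamples. By default the
resampling unit is the child (both sides move together), which prevents a
twin-row of the validation record from sitting in the training set; record
level resampling is available to mirror pure record bootstrap. The same
resamples serve hyperparameter tuning (selection by pooled out-of-bag
weighted Brier, ties to the simpler grid point) and reporting, accepting
the slight optimism of reusing them. Default grids: 500 trees with
`mtry` in {√p, p/3, p/2}; elastic-net mixing in {0, 0.25, 0.5, 0.75, 1}
crossed with penalty strengths {0.001, 0.01, 0.1}.

Classification metrics (misclassification, sensitivity, specificity) use a
0.5 threshold; the threshold is a reporting convention, not part of
training, and is configurable.

## Probability calibration

Because the probability is the primary output, pooled out-of-bag
predictions are recalibrated with isotonic regression, itself trained under
an out-of-bag bootstrap scheme: 25 bootstrap isotonic fits on the pooled
(prediction, class) pairs are averaged pointwise on a 201-point grid. An
average of monotone maps is monotone, so the calibration map is monotone
non-decreasing with range inside [0, 1] by construction. Between isotonic
knots the map interpolates linearly and clamps outside the observed range.
Calibrated and raw metrics are always reported side by side, since
calibration can occasionally hurt.

## Explanation

Variable importance is the forest's total impurity decrease, or the
absolute standardized coefficient for the elastic net, rescaled so the top
predictor scores exactly 100. Patient reports show the calibrated
probability, its complement, and the values of up to five predictors with
relative importance of at least 10 (the cutoff operationalizes "enough
weight"; the top predictor is always shown). Partial dependence curves are
computed by overwriting one predictor across the training rows and
averaging the calibrated prediction, reported on both the raw and the log
probability scale (the display convention for these plots); binary feature
predictors yield two-point curves.

## The synthetic generator

No clinical data ship with the package, so every stage is exercised on
synthetic data with known structure.

**Typical curves.** Each joint/plane has a smooth analytic base shape with
realistic magnitudes (knee flexion: loading bump near t = 15, swing peak of
about 60 degrees at t = 70; ankle: first-rocker plantarflexion dip, second
rocker dorsiflexion peak, push-off, swing recovery; and so on), with
foot-off fixed at 60%. Subject variation uses an *antithetic balanced
design*: subject j carries a sign z_j = ±1, balanced across the cohort,
the right side uses −z_j, and the curve is
`(1 + eps·b)·base + eps·offset` with `eps = side_sign · z_j`. Every
location or scale statistic read by a detector then deviates from the
cohort mean by exactly one magnitude, which is strictly smaller than the
band's sample SD (the n/(n−1) factor), so *all 49 features are absent on
every unperturbed typical trial by construction* while the bands retain
realistic nonzero spread. This is the margin that makes the
49-feature trigger/non-trigger suite deterministic. The price is
deliberate unrealism: no within-curve measurement noise, no timing
variability, only two effective curve shapes per joint. Passing tests
therefore demonstrate the detectors' contract (thresholds, windows,
strictness), not robustness to real marker noise or gait variability.

**Implantation.** `implant_feature()` modifies only the curves a feature
reads, using smooth tapered window shifts, amplitude scaling about the
mean, shape replacement or sign flips, targeted to exceed the detection
threshold by at least half a band SD (with a 0.5-degree floor). Related
detectors on the same curve may legitimately co-fire (lowering mid-stance
dorsiflexion also increases plantarflexion), which mirrors how the rules
overlap clinically; the trigger suite asserts only target presence and
typical absence.

**Clinical cohorts.** Children (two sides each) receive examination values
from plausible clinical ranges, with height and weight tied to age. Labels
are drawn from a logistic model on three standardized active predictors
(default odds ratios 3.5 per SD, a strong but clinically plausible signal),
with the intercept solved numerically to hit the target prevalence (default
0.3). One kinematic feature per outcome is implanted with probability 0.7
in positive records and 0.05 otherwise, linking the kinematic channel to
the label. Missingness is completely at random (default 5% on
non-anthropometric columns), matching the assumption under which
median/mode imputation is coherent; real clinical missingness is unlikely
to be random, which is a known limitation of the simple imputation scheme.
Patient-trial curve perturbations are continuous (truncated normal signs),
so occasional incidental feature flags occur in patients, as in real data.

## Validation problem sizes and expected behavior

The shipped validation uses a 30-subject reference cohort for the band and
trigger suites; 250-child cohorts (500 records, 25 resamples) for the
permutation-null checks; a 500-child cohort (1000 records) for
signal recovery; and 10^5 pairs for the calibration identity check. These
sizes keep the full suite within minutes on one CPU while leaving the
statistical conclusions stable across seeds.

Two behaviors deserve explanation. On label-shuffled data, models that
maximize likelihood or purity predict the base rate, and at prevalence 0.3
a constant base-rate predictor has weighted Brier ((1−π)² + π²)/2 ≈ 0.29 —
within, but near the top of, the 0.25 ± 0.05 null band; the stratified
forest, which trains balanced, sits near 0.26. This gap between 0.25 and
0.29 is exactly the class-imbalance phenomenon the weighted metric is
designed to expose. On the strong-signal cohort the calibrated random
forest reaches weighted Brier ≤ 0.20 with sensitivity ≥ 0.70 and
specificity ≥ 0.80 at the 0.5 threshold, and the elastic net recovers the
signs of the generating coefficients.

## Numerical and degenerate-input choices

* All band comparisons are strict; equality is absent. Detector evaluation
  contains no randomness: identical inputs give identical feature vectors.
* Peak/pit searches on constant or monotone curves return "none"; a
  zero-variance curve or template contributes correlation 0.
* `extremum` ties (equal extreme values) resolve to the earliest t.
* Mode imputation ties resolve lexicographically.
* Bootstrap in-bag resamples that miss a class are redrawn
  deterministically (derived sub-seeds), at most 100 times.
* A reference cohort with an odd subject count assigns one subject the
  neutral sign; even counts give the exact balance that guarantees the
  typical-trial margin.
* All randomness flows from a single integer seed per entry point;
  sub-seeds are derived arithmetically, and artifacts embed the seed and a
  configuration hash.

## Known limitations

The detectors inherit the fragility of fixed windows under markedly
abnormal walking speed (no time warping); the analytic templates are
stand-ins for unpublished clinical exemplars; the generator does not
emulate measurement noise, multi-trial variability, or
missing-not-at-random examination data; and models trained on one center's
labeling style are, by design, a portrait of that style rather than a
transportable clinical ground truth.
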