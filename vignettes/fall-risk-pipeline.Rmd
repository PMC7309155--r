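---
title: "Predicting fall risk from wearable IMU gait recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting fall risk from wearable IMU gait recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the data

Falls are a leading cause of injury and death in people over 65, and
nursing-home residents fall far more often than home-based elderly. The
clinical workhorse for screening is the Timed Up and Go test (TUG): the
time to stand up, walk 3 m, turn, and sit down, with longer times
indicating higher risk. A stopwatch number, however, says nothing about
*how* a person walks. This package implements an analysis pipeline in
which a six-minute walking test, instrumented with a single lumbar
inertial measurement unit (IMU), supplies that missing information.

A recording is six synchronized channels sampled at 100 Hz:
accelerations `a_ml`, `a_v`, `a_ap` (mediolateral, vertical,
anteroposterior; m/s²) and angular velocities `w_ml`, `w_v`, `w_ap`
(°/s). The walking track is point-to-point with turnarounds roughly
every 25 m, which show up as regularly spaced bursts in the vertical
angular velocity. Each participant carries a binary label: *faller* if
they fell at least once during a six-month follow-up. The reference
cohort composition is 23 fallers and 50 nonfallers.

Three classifiers are built on this material:

1. **TUG** — a single threshold on the TUG time, placed at the maximum
   of Youden's index Se + Sp − 1 along the ROC curve.
2. **TUG+** — a three-question checklist combining the TUG threshold
   with two gait-variability thresholds (is SDa_ap above its cut? is
   Da_v below its cut?), fitted by exhaustive in-sample grid search.
3. **CNN** — a small convolutional network fed 20-s windows of the raw
   six-channel signal; a participant's risk is the mean of their frame
   scores, with risk declared above 0.5.

## Variability indices

For every channel two numbers summarize gait variability over the full
recording (turnarounds included):

* **SD** — the sample standard deviation (denominator N − 1): the
  *magnitude* of fluctuations, in channel units.
* **D** — the box-counting fractal dimension of the graph of the
  series: its *complexity*, between 1 (smooth) and 2 (maximally
  irregular).

The dimension estimator maps the graph to the unit square (min–max
normalization of both axes, which makes the estimate invariant to
affine amplitude changes and comparable across channels with different
units), overlays dyadic grids of side ε = 2⁻ᵏ for k = 2…9, and
regresses log N(ε) on log(1/ε) over k = 3…8, avoiding the saturated
coarsest and finest scales.

Two numerical choices matter and are deliberate:

* **Covering count.** Within each time column the piecewise-linear
  graph covers a vertical interval; we count the *grid lines crossed*
  by that interval, `floor(ymax/ε) − floor(ymin/ε)`, rather than the
  occupied cells (one more per column). Under a uniform grid offset the
  crossing count has expectation exactly span/ε, whereas the
  occupied-cell count adds a +1 per column that inflates coarse-scale
  counts and biases the slope low. On 36 000-sample fractional Brownian
  motion (fBm), whose graph has dimension 2 − H, the crossing-count
  estimator recovers the theory with |bias| < 0.05 across
  H ∈ [0.2, 0.8]; the occupied-cell variant is 0.06–0.10 low. A
  straight line measures ≈ 1.03.
* **Scale window.** With k = 3…8 on a 360-s recording, the analysis
  window spans box columns of 1.4–45 s. Structure *faster* than the
  window — e.g. a pure 0.85-Hz stride oscillation — fills its columns
  vertically and registers as space-filling (D → 2). Measured D at
  these scales is therefore a statement about roughness at
  second-to-minute scales, not about the sample-to-sample smoothness of
  the stride cycle. This is why a mostly-periodic signal does *not*
  measure D ≈ 1 here, and why the synthetic generator controls D
  through its noise component (below).

Degenerate inputs: a constant channel is defined to have D = 1 (flat
line) with a warning; estimates outside [1, 2] by more than 0.05 warn
rather than clip.

## The synthetic cohort generator

The study that motivates this pipeline deposited no raw recordings, so
the package ships a generator whose cohorts reproduce the published
group statistics, making every downstream stage testable end to end.
Each channel is

> stride-periodic carrier (3 harmonics of 0.85 Hz, random phases)
> + fractional Brownian roughness (Hurst exponent H),

mixed so the fBm component carries `noise_fraction = 0.9` of the
variance, then rescaled *post hoc* so the sample SD equals the
participant's drawn SD target exactly (to < 1e-9). The vertical angular
velocity additionally carries Gaussian turnaround bursts (default:
every 30 s — a 25-m track at a slow elderly pace of ~0.85 m/s — width
1.5 s, peak 90 °/s).

Group targets come from the published cohort tables:

* Fallers: median SDa_ap 0.120 m/s², median Da_v 1.78, TUG quartiles
  23 [19–31] s.
* Nonfallers: SDa_ap 0.090 m/s², Da_v 1.81, TUG 19 [16–25] s.
* All channels without a significant group contrast share the
  nonfaller medians and quartile spreads, so they stay
  indistinguishable between groups by construction.

Between-participant SD targets are lognormal with log-σ fitted from the
printed quartiles (`fit_lognormal_from_quartiles()`: μ = log median,
σ = log(q3/q1)/2z₀.₇₅ — exact when the quartiles are log-symmetric,
the symmetric-in-log compromise otherwise, with the residual landing in
the quartiles and never in the median). TUG times use the same
construction; TUG and IMU draws are independent by default
(`tug_imu_correlation` exposes a Gaussian-copula knob).

**Hurst calibration.** The generator must hit *measured* dimension
targets, but the estimator's output on a carrier+fBm mixture is not
2 − H: the carrier pressure toward 2 and the finite-sample bias both
shift it. `calibrate_hurst()` therefore Monte-Carlo-maps a grid of H
values to mean estimated D under the exact study geometry (360 s,
100 Hz, noise fraction 0.9) and targets are inverted through an
isotonic fit of that curve. Two facts shape the defaults:

* D(H) is monotone *decreasing* only while the fBm component dominates
  the mid-scale box columns; at noise fractions ≤ 0.8 the carrier's
  saturation wins at high H and the curve turns back up. The default
  grid H ∈ [0.05, 0.325] at noise fraction 0.9 is the monotone branch,
  covering measured D ≈ 1.75–1.87.
* The w_v target (1.74) sits slightly below the reachable floor; it is
  clamped to the boundary with a warning. Both groups share that
  target, so the clamp cannot create a spurious group difference. The
  turnaround bursts compress the w_v walking band after min–max
  normalization and lower its measured D further — again equally in
  both groups.

The calibration is a design constant (internal fixed seed), computed
once per session and cached; `default_hurst_calibration()` exposes it.
Because dimension targets are groupwise constants, a group's D spread
across participants is pure estimator noise (σ ≈ 0.02–0.03). That is
narrower than the published interquartile ranges, which is the main
acknowledged gap between synthetic and real cohorts: real
between-participant complexity variation is collapsed to a point. The
consequence is that group separation on Da_v is *easier* in synthetic
data than in the study, so classifier accuracies here bound behaviour
on real data from above, and passing tests demonstrate correctness of
the machinery, not clinical performance.

Other simplifications: no pauses, no walking aids, no joint kinematics,
stride frequency common to both groups, and an fBm (nonstationary)
roughness component — its slow wander emulates postural drift but makes
6-minute traces drift more than typical real recordings.

## Threshold classifiers

`roc_curve()` builds one operating point per distinct score for the
rule "risk if score > t"; its trapezoidal AUC equals the tie-corrected
concordance statistic exactly, which ties it to the Mann–Whitney U used
for the group tests (U = n₁n₀·AUC). `youden_threshold()` maximizes
Se + Sp − 1 over candidate cuts placed at midpoints between adjacent
distinct scores (plus sentinels beyond both extremes), breaking ties
toward the lower (more sensitive) cut; midpoints make the fitted rule
invariant to infinitesimal perturbation of the scores. All
classification comparisons are strict (a score exactly at the cut is
negative).

`fit_tugplus_thresholds()` keeps the TUG cut fixed, then exhaustively
searches the midpoint grid for the (SDa_ap, Da_v) pair maximizing
in-sample accuracy — deliberately reproducing a full-population fit
with no cross-validation, because that is how the clinical rule was
designed; a held-out evaluation is the caller's responsibility. Since
the grid includes cuts beyond the observed extremes, the TUG-only rule
is in the hypothesis space and the fitted TUG+ can never be less
accurate in-sample. The default combination is the disjunction (any of
the three questions positive ⇒ risk): a sequential refinement of
TUG-positives can only lower sensitivity, and the published Se increase
of the augmented test (0.714 → 0.857) is only reachable by a rule that
can flag TUG-negatives; the sequential variant remains one argument
away (`combine = "sequential"`). `logistic_fusion_fit()` provides the
model-based alternative on the same three features, with a lightly
ridge-penalized fallback (λ = 1e-4) under perfect separation.

Diagnostic evaluation follows the standard seven statistics (Se, Sp,
PPV, NPV, Acc, LR±) with undefined ratios flagged explicitly. The
Mann–Whitney test uses the exact distribution for small untied samples
(min n ≤ 8) and the tie- and continuity-corrected normal approximation
otherwise. McNemar's comparison of two classifiers on the same
participants uses the exact binomial test on the discordant counts
below b + c = 25 and the continuity-corrected χ² above.

## The CNN classifier

Frames are 20-s windows (2000 samples × 6 channels); training data
uses 10-s overlap to enlarge the set and wash out frame-start bias,
held-out data uses non-overlapping frames. The test split is 8 fallers
+ 8 nonfallers drawn at random; training is the complement, and no
participant contributes frames to both sides. The architecture is three
conv stages (8, 16, 32 filters; 3-channel × 5-sample kernels; the first
stage strides by 4; max-pool by 4 along time), global average pooling
to one feature per filter, and a three-layer dense head (32 → 16 → 1,
sigmoid), trained with Adam on class-weighted binary cross-entropy.
Training is fully seed-deterministic. The convolution engine is written
in R on top of BLAS (im2col + matrix products).

Three preprocessing/regularization choices carry the generalization
burden, because 57 training participants is tiny by deep-learning
standards and a flexible network happily memorizes participant
identities instead of group structure:

* **Per-frame centring** removes each frame-channel's mean: a worn
  sensor's baseline (gravity projection, gyro bias, slow drift) is
  position- and participant-specific and carries no group information,
  yet dominates raw convolution responses.
* **Per-frame unit-SD normalization** (`frame_scale = "frame"`,
  default) makes the network read waveform *shape* — spectral content
  and roughness — rather than amplitude. Each participant's drawn
  amplitude vector is a unique signature and is exactly the feature a
  memorizing network latches onto; normalizing it away forces the
  scale-free complexity contrast to do the work. With
  `frame_scale = "global"` (training-set scaling, amplitudes kept) a
  lognormal gain-jitter augmentation (`aug_scale_sigma`) is available
  to the same end.
* **Global average pooling** removes the spatial degrees of freedom a
  dense head could use to memorize frame positions.

Early stopping monitors participant-level balanced accuracy (the
quantity the experiment reports) on a held-out quarter of the training
participants, with the weighted frame loss as tie-breaker, and restores
the best weights. With the defaults a full experiment on the 73-subject
cohort trains in roughly one to three minutes on one CPU core.

On default synthetic cohorts the experiment reaches median held-out
accuracies above the published 0.75 (the suite asserts the median over
five seeds); on a zero-contrast control cohort (both groups drawn from
nonfaller parameters) it collapses to the majority class and scores at
chance, confirming no leakage path. The related monotonicity claim —
doubling the group contrast never lowers median accuracy — is exercised
only through this contrast/no-contrast pair rather than a full sweep,
which would cost ten further training runs for little additional
information.

## Problem sizes used by the test suite

Structural tests run on miniature cohorts (40-s recordings at 50 Hz,
with dimension targets re-calibrated for that geometry, since short
signals measure lower D). The end-to-end checks use the full study
conditions: one 23 + 50 cohort of 360-s recordings at 100 Hz, five CNN
seeds on it, one control cohort, a five-point fBm sweep at 36 000
samples, and group-contrast checks on 120-s cohorts (SD draws are
duration-free and the dimension gap survives shortening). The
acceptance script reports cohort medians from one full cohort plus
eleven replicate faller groups (SD) and five replicate TUG draws.

## Known limitations

* Measured D depends on the estimator's scale window; values are
  comparable within this pipeline but not across box-counting variants
  with other normalizations or fit ranges.
* The generator reproduces medians and quartile spreads of the index
  distributions, not full joint distributions; D spread within a group
  is estimator noise only, and stride morphology is three harmonics,
  not biomechanics.
* TUG+ thresholds are in-sample by design; reported in-sample
  accuracies are optimistic for new cohorts.
* The CNN's default preprocessing discards amplitude information; on
  data where magnitude (not complexity) carries the group signal,
  switch to `frame_scale = "global"` with gain-jitter augmentation.
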