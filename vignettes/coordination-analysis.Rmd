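---
title: "Quantifying head–trunk coordination in immersive steering and JAR tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying head–trunk coordination in immersive steering and JAR tasks}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordkin)
```

## The measurement problem

A participant wearing a head-mounted display steers a simulated flight
at a constant 12 m/s through a course of coins 58 m apart, using either
head or torso movements. Ascent and descent map to flexion/extension of
the controlling segment; turns map to a linear combination of lateral
flexion (roll) and axial rotation (yaw). Head and torso orientations
are recorded as intrinsic Tait–Bryan angles (pitch/roll/yaw, degrees),
zeroed at a self-selected neutral pose, at a 68 ms sample period. A
companion joint-angle-reproduction (JAR) task asks the participant to
bring the head or the torso to 0° or ±15° with or without explicit
visual feedback, in 4 s trials.

The scientific questions — does the upper body move "en bloc" or
segmentally, how precisely is each segment positioned without vision,
and does segment coordination predict steering skill — are answered
through a battery of per-sequence kinematic variables, a variable
selection step, and repeated-measures inference. This vignette
documents the models, conventions and parameter choices behind each
stage, and what the synthetic validation does and does not establish.

## Conventions chosen where the measurement chain leaves them open

**Angle signs.** Positive pitch = flexion (down-steer), positive roll =
right lateral flexion, positive yaw = right axial rotation. The
acquisition convention is device-dependent in practice, so the package
fixes one consistently and documents it; every statistic in the battery
is either sign-invariant (amplitudes, absolute correlations, DTW) or
reported with its convention (cross-correlation lags, JAR signed
errors).

**Euler order.** The rotation order of the acquisition devices is
upstream of this package (quaternion-to-Euler conversion is assumed
done); the package treats the three angle channels as given traces.

**Canonical file format.** Plain CSV plus a JSON metadata sidecar,
written to 12 significant digits: in a small-data domain,
inspectability beats binary containers, and the format round-trips
byte-stably. Time is stored in seconds (0.068, not 68).

## Course geometry

The ideal path through the coins is a *centripetal* (α = 0.5)
Catmull–Rom spline. The centripetal parameterization is chosen because
it cannot produce cusps or self-intersections inside a span, which
uniform Catmull–Rom can on tight turn sequences. Endpoints are handled
with reflected phantom points (P₀′ = 2P₁ − P₂): duplicating endpoint
knots — the other common convention — collapses the centripetal knot
interval to zero and is numerically undefined, so reflection is used
instead.

A coin's *crossing plane* is the vertical plane through the coin center
perpendicular to the ideal-path tangent at that coin (i.e. the plane is
anchored to the intended trajectory, not to the instantaneous flight
direction, which would make the error metric depend on the error
itself). The crossing point is linearly interpolated between samples
and the error is the in-plane distance to the center; an option
computes the full 3D distance instead. When a plane is never crossed
the error at the closest approach is used and flagged, and missed coins
are *included* in the error summaries by default — excluding them would
reward flying past coins.

The synthetic course generator alternates straight spans with one of
four maneuvers (right/left turn of 20°, ascent/descent of 12°), drawn
at random. Cumulative azimuth is clamped to ±45° and elevation to ±18°,
mirroring a maneuver that would exceed the bound: this keeps the
steering command inside a physiological body-angle range and keeps the
course qualitatively like a game course that must remain flyable.

## Segmentation and artifact rejection

Sequences are split at the interpolated plane-crossing times; a course
with *n* coins yields *n* − 1 segments whose durations exactly
partition the in-course time. A segment is rejected when any
consecutive-sample angular change on any axis of either segment
*exceeds* 20° — strictly: a jump of exactly 20.0° is kept. Such jumps
arise from radio interference with the inertial sensors, not from
movement (20° in 68 ms would be ≈ 300°/s sustained). Rejected segments
are excluded from the per-sequence averages and their count is
reported.

## The descriptive battery

Fifty variables are computed per valid segment and arithmetically
averaged over the sequence; per-segment values that are undefined
(e.g. a correlation of a flat trace) are ignored rather than
zero-filled, which would bias averages toward null values. Conventions
worth recording:

* **Amplitudes** are interquartile ranges with linear-interpolation
  (type-7) quantiles.
* **Error summaries** (three slots) are the mean, median and maximum of
  the per-coin crossing errors over the sequence; the path ratio is
  computed once per sequence on the trajectory clipped between the
  first and last plane crossings.
* **Correlations** are absolute Pearson correlations of the *angle*
  traces (an option computes them on rates instead).
* **Anchoring index** Δσ = (σ_r − σ_a)/(σ_r + σ_a), σ_a the SD of the
  head angles in space and σ_r the SD of head-minus-torso. It is
  bounded in [−1, 1], invariant to shared offsets, and equals
  (√2 − 1)/(√2 + 1) ≈ 0.172 for independent equal-variance head and
  torso — a useful mental null.
* **Cross-correlation lags** use Pearson-style per-lag normalization
  over the overlapping samples, searched within ± half the segment
  length (longer lags have too few overlapping samples to be
  meaningful); ties break toward zero lag. Negative values mean the
  head leads.
* **DTW distances** first resample both traces to a common length
  (default 64, near the typical per-segment sample count) so that the
  cumulative path cost is comparable across segments, then run
  unconstrained classic DTW with absolute-difference cost and the
  symmetric step pattern (implemented in C++; validated against an
  exhaustive warping-path enumeration).
* **SAL** (spectral arc length) is computed per torso axis on the
  rate profile: zero-padding 4 levels past the next power of two, a
  10 Hz cutoff and a 0.05 adaptive amplitude threshold, following the
  established adaptive-SAL parameterization. The value is ≤ 0; more
  negative = jerkier. The DC normalization makes it
  amplitude-invariant.
* **Peak counts** use a 1° prominence threshold — above sensor noise,
  below voluntary movement — normalized by segment duration. The
  "bird" (flight) peak counts are computed on the trajectory's heading
  angles: azimuth, elevation, and a coordinated-turn bank angle
  tan(bank) = v·ω/g; an option uses position components instead.
* **Speed ratios** mean/max of |rate|; 1 for constant-rate movement.

## Variable selection by weighted PCA

Sequences × variables are z-scored (constant variables dropped with a
warning). Outliers are observations whose Euclidean distance to the
centroid exceeds the mean distance by more than 4 SDs of the distance
distribution; they are kept but downweighted to 0.5 in the weighted
covariance, so a single corrupted sequence cannot rotate the leading
components while genuine extreme behavior still contributes. The PCA is
an eigendecomposition of the weighted covariance with a deterministic
sign convention (largest-magnitude loading positive), making the whole
pipeline bit-reproducible.

"Normalized loadings" are each component's loadings divided by that
component's maximum absolute loading, so the 0.75 selection threshold
is scale-free; an alternative normalization (raw unit-norm eigenvector
entries) is selectable. Selection examines PC1 for the all-trials and
head-controlled subsets and PC1 + PC2 for the torso-controlled subset,
where the second component carries an additional age-related axis.
Outlier weights are recomputed per subset, since an observation extreme
within all trials need not be extreme within its subset. The selected
variables are grouped into *a priori* functional clusters by their
catalog category (error, head movements, torso movements, head–torso
coordination, trajectory) — the grouping is semantic metadata, not a
clustering algorithm, because the categories are defined by what each
variable measures.

## Inference

Each response is screened with the Anderson–Darling test at α = 0.05
and Box–Cox transformed (maximum-likelihood λ on a fine grid, values
shifted positive first) when normality is rejected; the transform is
applied to the response of the analysis as a whole, not per cell, so
group comparisons remain on one common scale. The mixed
repeated-measures ANOVA uses the classical univariate `aov()`
error-stratification with age as the between-subjects factor and
control and/or phase as within-subject factors; partial η² =
SS_effect/(SS_effect + SS_error) with the error term of the effect's
stratum. No sphericity correction is applied: the classical univariate
tables are reported as-is, keeping the implementation exactly checkable
against a hand-worked sums-of-squares oracle, and the within-factor
designs analyzed here have at most three levels, where the correction
is smallest. The training phases are excluded from the ANOVA by
default to keep the within-design balanced. Pairwise contrasts report pooled-SD
Cohen's d (unpaired) or difference-SD d (paired).

The false-discovery-rate control is the adaptive two-stage
Benjamini–Krieger–Yekutieli step-up: stage 1 runs a linear step-up at
q′ = α/(1 + α) to estimate the number of true nulls m₀ = m − r₁; if
anything but none or all are rejected, stage 2 re-runs the step-up at
q′·m/m₀. The implementation is validated against a step-by-step manual
trace, not against another package, and the family over which the rate
is controlled is an explicit input (the default chain uses the
age-effect p-values across analyzed variables).

## JAR metrics

The final orientation is the mean of the task-relevant axis over the
final 1.5 s of the 4 s trial — on the 68 ms grid this is the samples
whose stamps fall in the closing window (22–23 samples); an
interpolated-boundary alternative agrees within 0.05° on smooth traces.
The *task-relevant axis* for the lateral ±15° targets is the same
linear combination of roll and yaw used by the steering mapping
(single-axis options exist); the 0° target is treated as a lateral
target. Signed error = final − target (positive = exceeding).
Overshoot is the maximal excursion beyond the target *in the target's
direction* (relative to the target, not to the final angle). The
oscillation count — a quantity the protocol names but does not define —
is the package's convention: sign changes of (angle − final angle)
after the trace first enters a ±1° band around the final angle. For
torso trials the head anchoring index is computed over the whole trial,
plus the final head-torso difference (negative = head smaller) and the
head alignment error (final head − target). Lateral targets are pooled
by mirroring the sign-dependent metrics of −15° trials.

## The synthetic generator

The generator is kinematic, not biomechanical — no masses or inertias —
because its job is to exercise every downstream statistic with known
ground truth, not to model physiology. Three parameters carry the
coordination structure:

* **coupling c ∈ [0, 1]** — fraction of head motion rigidly following
  the torso; c = 1 is a perfect en-bloc strategy.
* **overshoot gain g > 0** — multiplicative bias on the commanded
  amplitude; g > 1 models proprioceptive overestimation of one's own
  movement.
* **compensatory head gain h ≥ 0** — instantaneous proportional head
  opposition (−h·torso) to the torso displacement (a lagged variant is
  available but off by default).

A flight trial tracks the ideal-path tangent at the arc position
travelled at 12 m/s: the commanded controller angles follow the
required angles through a first-order lag (τ = 0.4 s by default) scaled
by g, and the position is integrated with the heading set by the
(noise-corrupted) controller angles through the steering mapping
(azimuth = 2 × lateral angle; elevation = −pitch). With head control
the visual coupling corrects most of the proprioceptive bias, so the
effective gain is 1 + 0.3(g − 1); with torso control the full gain
applies. The non-steering segment mixes the coupled component
(c − h)·controller, an independent smooth gaze process (Gaussian noise
smoothed with a 0.5 s kernel, SD 3° by default — no head-movement
spectrum is claimed, only smoothness on a fixation timescale), and
white angle noise (SD 1.5°).

A JAR trial ramps (minimum-jerk, 1.2 s) to g·target when visual
feedback is absent — torso trials overshoot by (g − 1)·target, head
trials undershoot with gain 1/g — adds a settling oscillation that
fully decays before the final window, and noise. The default cohort
parameters decrease g and h and increase c with age (6-year-olds:
c 0.40, g 1.40, h 0.40; adults: c 0.85, g 1.05, h 0.05, SD 0.08),
reproducing the qualitative developmental pattern: younger groups
overestimate torso movements, compensate with the head, and couple the
head to the torso less tightly during torso steering. The default
protocol is the full study design: per control body part, sequences of
26/50/50/18 coins on day one and 26 on day two; JAR repetitions 5
(Feedback) and 10 (NoFeedback, Forward) per orientation; group sizes
9/12/11/13.

**What the generator does not emulate.** Real recordings contain
drift, quaternion-unwrapping glitches, fatigue and learning effects,
and genuinely closed-loop error correction; the generator's tracking is
open-loop around the ideal path, so crossing errors grow with course
length when g deviates from 1 rather than being re-corrected. Passing
the pipeline's parameter-recovery tests therefore shows the *statistics
measure what they claim on data with known structure* — it does not
certify recovery rates on human data.

## Numerical choices and degenerate inputs

Uniform time grids are enforced to 1e-9 s; non-uniform input files are
linearly resampled to the 0.068 s grid and flagged. Correlations,
anchoring indices, lags, SAL and speed ratios of flat traces are
reported missing, not zero. Constant variables are dropped before PCA;
rank-deficient PCAs report the effective component count. The weighted
PCA sign convention and the zero-lag tie-break make repeated runs
bit-identical. Quantiles are type-7 throughout.

## Problem sizes used in validation

The packaged tests and the acceptance script run the full chains on
scaled cohorts — 12–16 participants, 8–12-coin evaluation courses,
reduced JAR repetitions, and a 10–20-replicate recovery sweep of 8
coupling levels — sizes chosen so the whole validation suite runs on a
laptop in minutes while leaving every pipeline stage exercised end to
end. The generator's *defaults* remain the full study protocol; the
scaled runs simply pass smaller arguments.

## Known limitations

* The mixed ANOVA assumes sphericity unless the correction option is
  used, and balanced within-designs after listwise deletion.
* The JAR relevant-axis default (the steering combination) is a
  modeling choice; single-axis reanalysis is available but the two are
  not identical when roll and yaw contribute unequally.
* DTW cumulative cost depends on the common resampling length; compare
  only values computed with the same `target_length`.
* The open-loop flight simulator exaggerates late-course errors for
  g ≠ 1 (see above); error *orderings* across conditions are
  meaningful, absolute magnitudes are generator-specific.
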