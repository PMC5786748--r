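---
title: "Methods: posturography of self-triggered weight lifting"
author: "liftpost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posturography of self-triggered weight lifting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftpost)
```

## The measurement problem

A standing subject lifts a light barbell (0.5--1 kg, under 2% of body
weight) from a hanging position through a fast quarter circle to a
90-degree forward extension, holds it there for about five seconds, and
lowers it again, repeating the lift several times in 30-s recording runs
with eyes open (EO) or closed (EC).  The ground-reaction force is measured
by a four-sensor piezoelectric platform at 40 Hz, and a one-axis
accelerometer inside the barbell tracks the lift itself.  Because the lift
is self-triggered, the centre of foot pressure (COP) --- the point of
application of the ground-reaction force, a standing-posture surrogate for
centre-of-mass motion --- shows both *anticipatory* postural adjustments
(APA, before movement onset) and *compensatory* ones (CPA, after onset).
The scientific payload is how the post-onset COP trajectory differs between
healthy controls (CTR), idiopathic Parkinson's disease with falling history
(IPD), and progressive supranuclear palsy (PSP).

The package implements the full chain:

1. **COP computation** (`compute_cop`): the vertical-force-weighted centroid
   of the four sensor positions gives lateral `x` (positive rightward,
   toward the lifting arm) and anteroposterior `y` (positive forward); the
   third trace `z` is the normalized vertical load deviation
   `Fz/W - 1`.
2. **Barbell kinematics** (`calibrate_angle`, `angular_velocity`,
   `detect_lift_onsets`, `detect_markers`, `accept_trial`): the
   accelerometer is calibrated with the 0-g (hanging) and 1-g (horizontal)
   readings, so `theta = asin((acc - a0)/(a1 - a0))`; lift onset (marker
   "0") is the first negative peak of the derivative of the lightly
   smoothed acceleration; marker "a" is the latency of peak angular
   velocity and marker "b" the arrival at the 90-degree plateau.
3. **Segmentation and grand averages** (`segment_trials`,
   `baseline_correct`, `grand_average`): trials are cut to the half-open
   window [-1000, +5000) ms around onset (240 samples at 40 Hz),
   baseline-corrected, averaged trials-within-subject and then
   subjects-within-group, with a pointwise t band on subject means.
4. **Postural metrics** (`apa_window_means`, `cpa_peak`, `return_offsets`,
   `lateral_phase_indices`, `oscillation_frequency`, `kinematic_indices`).
5. **Group statistics** (`split_plot_anova`, `mauchly_test`, `gg_epsilon`,
   `bonferroni_posthoc`, `permutation_group_test`).
6. **A synthetic-cohort generator** (`group_template`, `generate_cohort`)
   whose defaults encode the published group signatures, with ground truth,
   so the entire chain is testable without any recorded data.

## The synthetic templates

No raw recordings of this paradigm are publicly deposited, so the generator
is a first-class part of the package: it defines the study conditions under
which everything downstream is validated.  Each group template is a
closed-form curve family --- sums of raised-cosine steps and bumps for the
COP axes, and a gamma-shaped pulse for barbell angular velocity --- so that
exact values exist at any time point and every injected quantity can be
recovered analytically.

The sagittal (forward) COP curve is a raised-cosine rise to the hold
plateau (the end-of-hold offset) plus a symmetric raised-cosine bump
centred on the peak latency.  The symmetric bump is deliberate: it makes
the curve's maximum sit exactly at the nominal latency, so that the latency
expressed by a grand average of jittered subjects is centred on the
template value (an asymmetric rise/decay pair whose decay starts with zero
slope lets the averaged peak drift late by more than 100 ms).

Template defaults (times ms after onset, amplitudes cm):

| parameter | CTR | PSP | IPD | anchored by |
|---|---|---|---|---|
| forward peak amplitude | 2.0 | 4.0 | 5.5 | free (CTR); patient peaks "by far higher" with PSP/IPD amplitudes comparable and offsets below |
| forward peak latency | 1200 | 1200 | 2600 | published landmarks (IPD lags PSP by 1.4 s) |
| end-of-hold offset | 0.5 | 3.0 | 5.0 | CTR < 1 cm; PSP in (2, 4]; IPD > 4 cm |
| backward onset dip | 0 | 0 | 1.0 | IPD-only backward shift at onset |
| rightward excursion | 0.6 | 0.15 | 0.4 | ipsilateral shift during arm acceleration |
| leftward hold lean | 0.8 | 0 | 0.4 | PSP lack the compensatory lean |
| oscillation | none | 1.3 Hz on x and z from 1500 ms, 0.45 cm | 0.3 Hz on x from 1000 ms, 1.0 cm | published wavelengths (0.75 s vs ~3 s) |
| peak angular velocity latency | 400 | 308 | 533 | PSP 1.3x, IPD 0.75x the control velocity |
| time to 90 degrees | 1200 | 923 | 1600 | control marker "b" at 1200 ms |

The control forward-peak amplitude of 2 cm is a free parameter (no
published value exists); only its ordering relative to the patient groups
and the control end offset matter for any test.

The barbell angular-velocity pulse is `omega(t) = 90 * dgamma(t; alpha + 1,
alpha / t_a)` deg/s with shape `alpha = 2.1956`, so the angle is the
corresponding gamma CDF scaled to 90 degrees.  The shape constant was
calibrated once so that, with the velocity peak at `t_a = 400` ms, the
angle crosses 95% of its plateau exactly at 1200 ms --- the two control
landmark latencies.  A raised-cosine velocity pulse cannot satisfy both
landmarks at once (its taper is too soft, putting the 95% crossing near
900 ms), which is why the barbell uses a gamma pulse while the COP curves
stay raised-cosine; closed-form evaluability is preserved in both cases.

Onset detectability is made well-posed by a one-sample negative transient
of 0.12 g added to the acceleration at each onset (a brief counter-jerk at
movement initiation), far above the 5-x-MAD trigger threshold.  Sessions
place lifts at random onsets separated by 10.0--10.8 s.  The separation is
generous for a reason: lowering the weight after the hold also produces
negative acceleration derivatives, and the detector disambiguates the two
by requiring a candidate to start below 45 degrees and to be followed
within 3 s by the angle exceeding 45 degrees; the spacing guarantees the
next lift's rise never falls inside the confirmation window of a lowering
artefact.

Between-subject variability is multiplicative Gaussian jitter (SD 5%,
factors clipped to [0.85, 1.15]) applied as one common factor per curve
family --- sagittal amplitudes, sagittal latency, lateral amplitudes,
oscillation amplitude, barbell latency --- so each subject keeps the group's
curve shape and the group ordering of every metric.  Measurement noise is
white Gaussian on the COP path (0.15 cm SD per axis at 40 Hz), on the
normalized vertical load (0.003) and on the accelerometer (0.0003 g).  The
accelerometer noise matters more than it looks: near the 90-degree plateau
the arcsine calibration is infinitely steep, so even small sensor noise
biases the *mean* plateau angle downward (half of the noise clips at 1 g,
the other half maps to visibly smaller angles), which drags the
0.95-of-plateau criterion --- and marker "b" --- earlier by roughly one
sample at the default noise level.

What the generator does *not* emulate: inverted-pendulum body dynamics,
EMG, stepping responses, tremor, or any EO/EC difference (the study found
none, so the two conditions are statistically identical in the generator).
Passing tests therefore demonstrate the correctness of the signal chain
under the encoded signatures, not robustness to every feature of clinical
recordings.

## Numerical and design choices

* **Vertical axis.** A static force plate cannot measure centre-of-mass
  height, so the "vertical displacement" channel is implemented as the
  normalized vertical force deviation `z = Fz/W - 1` with the quiet-stance
  load `W` estimated by the record median (most of a 30-s record is quiet
  stance).  The only analysis consuming `z` is oscillation frequency, which
  is invariant to this reading.
* **Filtering.** No filter is applied before the COP centroid; a zero-phase
  2nd-order 10-Hz Butterworth low-pass (on by default) runs afterwards.
  40-Hz sampling leaves little headroom, and all oscillations of interest
  are below 1.5 Hz.
* **Baseline.** Each trial subtracts its per-axis mean over [-1000, -900]
  ms, which leaves the four 250-ms anticipatory windows untouched by
  construction.  The published analysis never names its reference window;
  this one is the package's convention.
* **Confidence bands.** The band unit is the subject mean, not the trial,
  matching the repeated-measures design.  `ci_level` is per bound; the
  default 0.975 gives a two-sided 95% band, reconciling the "97.5%
  confidence intervals" and "95% CI" phrasings that both appear in the
  source description of this paradigm.
* **Trial rejection.** "Self-aborted" (never reaches 80 degrees), "slow"
  (onset to 80 degrees over 2500 ms) and "unstable-hold" (angle drops below
  70 degrees within 5 s of marker "b") are conventions of this
  implementation --- chosen to pass obviously complete lifts and fail the
  named failure modes --- and all configurable.
* **Markers.** Markers "a" and "b" are re-detected per group from the grand
  averages (argmax of omega; first crossing of 95% of the hold-phase
  plateau median over [2500, 5000) ms) rather than fixed at the control
  constants, and per trial for the metrics table.
* **Oscillation frequency.** The analysis window is [1000, 5000) ms (the
  return/hold phase; the published wavelengths are qualitative and name no
  window).  The series is detrended by a 2nd-order polynomial; extrema of
  the lightly smoothed residual whose swings exceed twice the noise MAD
  give the initial estimate `1/(2 * median inter-extremum interval)`, which
  is then refined by profiling a joint quadratic-plus-sinusoid least-squares
  fit over frequency, seeded by both the extremum and the periodogram
  estimates.  The joint fit exists because sequential
  detrend-then-count is measurably biased when the window holds close to
  one cycle: a quadratic absorbs part of a 0.3-Hz sine over 4 s and shifts
  the extremum spacing by 20--30%, while the joint fit recovers pure
  sinusoids exactly at any phase.  The estimate is flagged low-confidence
  when fewer than two prominent extrema exist, when the fitted amplitude is
  below twice the noise MAD, or when it disagrees with the periodogram peak
  by more than 30% beyond the window's Rayleigh resolution (1/T; a 4-s
  periodogram cannot localize 0.3 Hz any tighter).
* **Frequency estimation limits.** At 1.3 Hz (about five cycles per
  window) the estimator keeps within 10% of the injected frequency in
  every one of 200 seeded trials at oscillation-amplitude-to-noise ratio 3.
  At 0.3 Hz the window holds 1.2 cycles and the mandated quadratic trend is
  nearly collinear with the sine, so the frequency information itself
  collapses: even the profile fit (effectively maximum likelihood) is
  unbiased but with ~0.036 Hz standard error at ratio 3, reaching reliable
  10% recovery only near ratio 10.  Group grand averages, where this
  estimate is actually consumed, average hundreds of trials and operate far
  above that.
* **Split-plot ANOVA.** Implemented from first principles: the between
  stratum is a one-way decomposition of subject means; the within stratum
  uses orthonormal contrasts with Type-III (sum-to-zero) hypotheses so that
  unbalanced groups (16/15/17) test unweighted means.  Mauchly's W and the
  Greenhouse--Geisser epsilon come from the residual contrast covariance.
  The implementation is verified in the test suite against an independent
  brute-force sums-of-squares oracle and against `car::Anova`.  Note that
  the epsilon correction is only guaranteed conservative in the rejection
  region: for F below roughly 1.3 the corrected p-value can be *smaller*
  than the uncorrected one, because shrinking both degrees of freedom moves
  null mass toward zero.
* **Degenerate inputs.** Zero-variance responses give F = 0 (not 0/0);
  single-subject grand averages carry flagged NA bands; `k = 2` within
  levels make Mauchly inapplicable (W = 1) and epsilon exactly 1.

## Problem sizes

The default simulated design mirrors the study: 16/15/17 subjects, 20
sessions each (10 EO + 10 EC, alternating), 3 lifts per session --- about
960 analysed trials per group.  One full cohort generates and analyses in
a few seconds; the complete test suite, including the 200-replicate
coverage simulation and the 500-replicate type-I calibration, runs in
about two minutes on one core.

## Known limitations

* The published between-group p-values are not reproducible without the
  raw recordings; the statistics module reproduces the qualitative pattern
  (group effects on peak amplitude and latency, no EO/EC effect) on the
  synthetic cohorts instead.
* The printed "F(1,2) = 1.444" degrees of freedom of the source analysis
  are not derivable from the stated design; this package reports degrees
  of freedom from first principles and makes no attempt to match them.
* The accelerometer angle map ignores dynamic (tangential/centripetal)
  acceleration, treating the signal as position-equivalent, as the
  acquisition convention does; no inertial correction is attempted.
* Trial-level oscillation frequencies at 0.3 Hz are close to the
  information limit of a 4-s window (see above); interpret them only
  through the confidence flag, or at grand-average level.
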