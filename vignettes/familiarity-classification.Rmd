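---
title: "Classifying spatial familiarity from head and eye movements: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying spatial familiarity from head and eye movements: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wayfam)
```

## The problem

When a pedestrian follows a route they know well, their head and eye
movements differ from those of someone navigating unfamiliar streets:
wayfinders in unknown environments scan more ("looking around to orient
oneself"), fixate differently, and move their heads in characteristic ways
while deciding where to turn. **wayfam** implements a complete pipeline
that classifies a walking recording as *familiar* or *unfamiliar* from
wearable sensor streams alone:

1. a **synthetic session generator** producing gaze (200 Hz), head-IMU
   (400 Hz inertial / 100 Hz orientation) and GNSS (1 Hz) streams with
   configurable condition-dependent effect sizes,
2. **preprocessing** (zero-phase low-pass filtering, singular spectrum
   transformation change scores, artifact removal at a 10 m/s² free
   acceleration threshold, GNSS repair and route projection, downsampling
   onto the rotation clock),
3. **matching-to-action segmentation** into non-overlapping 3 s windows,
4. **feature extraction**: 28 gaze statistics and 99 IMU descriptors per
   window,
5. **gradient-boosted tree classification** with participant-aware
   validation, log-loss diagnostics and SHAP importance ranking.

The unit of classification is the 3 s window of a *matching-to-action
segment*: the stretch between the moment a walker requests a route
instruction and the moment they arrive at the junction the instruction
refers to. That is where instruction-triggered decision-making behavior
lives; the rest of the walk is not used.

## Why a synthetic generator is first-class

Real recordings of this kind are expensive and privacy-laden. The
generator is not a test fixture but the package's study-design instrument:
it defines *exactly which behavioral contrasts exist* between the two
conditions, so every downstream claim can be tested against a known
ground truth. Its signal model is:

* **Gaze**: a fixation–saccade renewal process. Fixation durations are
  log-normal (mean 250 ms, SD 100 ms); within a fixation the gaze point
  jitters uniformly within a condition-scaled half-width (default 0.003
  familiar / 0.0045 unfamiliar, normalized scene units). Bounded rather
  than Gaussian jitter is used so that a fixation's dispersion does not
  grow with its sample count past the I-DT threshold — the dispersion
  *level*, not the detector's break-up behavior, carries the contrast.
  Saccade amplitudes are gamma distributed (shape 2, condition-scaled
  scale); saccade displacements additionally carry the apparent scene
  shift induced by head rotation (yaw → x, pitch → y, mapped at 1/82
  normalized units per degree, the nominal 82° horizontal field of view
  of the scene camera).
* **Head IMU**: a gait sinusoid on the vertical free acceleration
  (default 1.8 Hz, with a second harmonic), lateral sway at stride rate,
  AR(1) orientation noise, and a slow condition-scaled yaw "scanning"
  oscillation (default 10° familiar / 20° unfamiliar at 0.15 / 0.25 Hz).
  Poisson-placed cap-touch artifact bursts (default 1/min) add a
  Gaussian-envelope transient whose dominant axis exceeds the configured
  peak (default 15 m/s²) — guaranteed above the 10 m/s² cleaning
  threshold so the preprocessing stage can be tested by injection.
* **GNSS**: the true position follows the route polyline at walking speed
  (1.4 m/s) with isotropic Gaussian noise (1.5 m default) and occasional
  `inaccurate`-flagged 20–50 m jumps emulating loss of RTK correction.
* **Participants**: each contributes one familiar and one unfamiliar
  recording sharing participant-level random effects (baseline yaw
  offset, SD 15°; gait-frequency jitter, SD 0.08 Hz).

Four families carry configurable, independent condition contrasts: yaw
dynamics, acceleration noise variance, fixation dispersion and saccade
amplitude. `null_effect_config()` equalizes all four (zero class signal);
`yaw_only_effect_config()` plants a contrast in yaw alone. What the
generator does **not** emulate: scene content, vestibulo-ocular dynamics
within fixations, terrain, stops at crossings, pupil data (deliberately —
outdoor luminance makes pupillometry unreliable). A pipeline that passes
all synthetic tests is therefore validated for its *mechanics and
statistical honesty*, not certified to reach any particular accuracy on
real street recordings.

## Preprocessing choices

The order is fixed and tested: low-pass filter → change scores →
classification → drop → downsample.

* **Low-pass filter**: zero-phase Butterworth, order 4, 5 Hz cutoff on
  the free acceleration. 5 Hz preserves the gait band (< 3 Hz) while
  removing ringing. `signal::filtfilt` alone leaves start-up transients
  (it uses zero initial conditions), so the implementation removes the
  mean and pads with an odd reflection of 3·fs/cutoff samples before
  filtering; a DC signal passes through bit-exactly.
* **Singular spectrum transformation (SST)**: at each evaluation point,
  past and future trajectory (Hankel) matrices (window 50 samples,
  lag 25, 16 columns, column mean-centered) are compared through their
  leading 2-dimensional singular subspaces; the score is one minus the
  mean squared principal-angle cosine. Stationary structured signals
  score near 0; abrupt changes score near 1 across a plateau of roughly
  window + columns + lag samples, whose *midpoint* localizes the change.
  On pure broadband noise the principal subspaces are random and the
  score is high everywhere — which is why the score only *gates* the
  artifact rule rather than replacing it. A `stride` argument evaluates
  every k-th sample with linear interpolation in between (the pipeline
  default is 12 at 400 Hz ≈ 30 ms resolution), purely a cost/resolution
  trade-off.
* **Undesired classification**: a sample run is undesired when the
  per-sample maximum of the three filtered |free-acceleration| channels
  exceeds 10 m/s² and a contemporaneous SST score peak confirms a
  structural change. Intervals are dilated ±0.25 s to cover burst
  shoulders, then merged. Raising the threshold never adds intervals
  (monotonicity, tested). Dropping removes IMU *and* gaze samples inside
  the intervals — eye movements recorded while the cap is being touched
  are equally contaminated — and leaves GNSS untouched.
* **Downsampling**: one row per 100 Hz rotation timestamp, each inertial
  channel taking its nearest-in-time raw sample (a sample-matching rule,
  not interpolation; for a ramp the error is bounded by slope/800 s).
* **GNSS repair**: `inaccurate` fixes are replaced by the weighted mean
  of the 2-before/2-after fixes with weights [1, 2, 2, 1]/6 (nearer
  neighbours doubled); flagged fixes within two samples of the ends are
  left unchanged with a warning. Tracks are then projected onto the
  route polyline (nearest point), after which the projected arc-length
  of a forward walk is almost surely non-decreasing.
* **Time-offset estimation**: for logs with only 1 s file-timestamp
  precision, a deliberate rapid head movement at coarse time `t_A` is
  refined by locating the yaw extremum (largest |yaw − window median|)
  within ±1 s; `delta_t = t_B − t_A`. A prominence floor (2° default)
  flags flat-yaw windows as unreliable.

## Feature banks

**Gaze (28)** — I-DT fixation detection (dispersion threshold 0.02
normalized units, duration threshold 100 ms; dispersion is
(Δx + Δy), the classic city-block extent): mean/min/max/var of fixation
duration, dispersion, dispersion-x, dispersion-y (16), fixation frequency,
mean/min/max/var of saccade amplitude and duration (8), saccade-amplitude
skewness (adjusted Fisher–Pearson), saccade frequency, and the g-l ratio
(count of saccades above / at-or-below the recording-median amplitude).
Saccade amplitudes are head-compensated: the shift predicted from the IMU
rotation delta over the inter-fixation gap is subtracted before taking
the norm. Variances need two events and skewness three; below that the
value is missing (the boosted trees accept missing values natively).

**IMU (99)** — six families over each 3 s window of the unified 100 Hz
stream: 31 basic statistics (min/max/mean/var of per-trial mean-centered
acc x/y/z and roll/pitch/yaw — centering absorbs mounting differences
between trials; yaw zero-crossing rate in crossings/s; point-to-point
amplitudes of acc and free-acc channels), 50 cepstral coefficients of the
acceleration magnitude (inverse FFT of log(|spectrum|² + 1e-12), c₀
included), 5 time-domain measures (SD, energy = Σx²/fs, min/max/
peak-to-peak amplitude), the fundamental period (minimum interval between
local maxima with topographic prominence ≥ 0.5·SD; missing below two
peaks — on noisy windows this is a roughness descriptor more than a
cadence estimate), 8 movement measures (movement-intensity mean/var,
signal magnitude area, per-axis energy, Shannon entropy of a 16-bin MI
histogram in bits, movement variation), and 4 spectral measures
(zero-crossing rate per sample pair, spectral centroid, 85% spectral
rolloff, chroma mean over 12 log-spaced bands from 0.5 Hz to Nyquist —
semitone bins are meaningless at 100 Hz, so log-frequency bands stand in).
Cepstral/time-domain/period/spectral features use the acceleration
magnitude √(ax² + ay² + az²). Every family is verified against an
independently coded, definition-level recomputation at 1e-9 relative
tolerance.

## Classification and validation

The learner is gradient-boosted trees (xgboost), deliberately *not*
reimplemented — the contribution is the pipeline around it.
Hyperparameters are searched by 10-fold cross-validation scored by mean
validation negative log-likelihood over a grid whose candidate values are
the union of configurations known to win on comparable data (subsample
{0.1, 0.4, 0.5}, estimators {100, 500, 700, 1000}, min child weight
{0.5, 0.6, 0.7}, depth {3, 6, 10}, learning rate {0.001, 0.01, 0.05,
0.1}, gamma {0.6, 0.7, 1.0}, column subsample {0.6, 0.7, 0.8, 1.0});
`n_search` draws a random subset for budgeted tuning, and the default
grid is a single fast configuration (no tuning). All boosting runs are
single-threaded and seeded: identical (data, grid, seed) reproduce
predictions to the last bit.

Two validation schemes:

* **80/20**: condition-stratified window-level split. Windows of the same
  participant appear on both sides, so accuracy is optimistic.
* **L5O4T** ("leave five out for testing"): per repeat, all windows of
  five random participants' *familiar* recordings plus five independently
  drawn participants' *unfamiliar* recordings are held out entirely —
  never in training nor in CV folds, enforced by assertion at fit time.
  Ten repeats with fresh draws; average/best/worst accuracies reported.

Before training, rows with any feature beyond 3 SD from the column mean
are removed; the filter is *fit on the training partition* and applied to
both partitions (fitting it on pooled data would leak test statistics
into training). SHAP importance uses TreeSHAP contributions on the
log-odds scale, averaged in magnitude; attributions are additive to the
prediction margin within single-float precision (~1e-4).

## Calibration properties

Two end-to-end properties replace real-data accuracy targets:

* **Null calibration**: with both conditions statistically identical, the
  held-out L5O4T accuracy must be statistically indistinguishable from
  0.5. Windows within a held-out recording are correlated, so the 95%
  interval is computed with one unit per held-out *recording*
  (10 seeds × 10 recordings), which is conservative.
* **Planted-signal recovery**: with a contrast planted *only* in yaw
  dynamics (familiar oscillation SD twice the unfamiliar), held-out
  accuracy must reach 0.85 and a yaw-family feature must occupy SHAP
  rank 1 in at least 9 of 10 seeds.

The calibration cohorts use 10 participants walking four-leg 35 m zigzag
routes (~100 s per walk, ~130 windows per cohort) with the default
single-configuration grid — sizes chosen to make a cohort a few tens of
seconds of compute so the properties can be evaluated across many seeds.

## Numerical and degenerate-input conventions

* All times are seconds, distances meters, angles degrees (yaw wrapped to
  (−180, 180]), gaze in normalized scene units (origin top-left, y down).
* Feature tables round-trip exactly through CSV (%.17g out, correctly
  rounded parse in).
* Empty gaze input yields an empty fixation list, not an error; windows
  shorter than 1 s yield an all-missing IMU row; a never-reached junction
  yields a structured "no arrival" (NA) and the event is skipped.
* Constant signals: zero variances and amplitudes, entropy 0, cepstrum
  kept finite by the ε floor, SST treats constant trajectory blocks as
  equal subspaces.
* Trailing window remainders shorter than 3 s are discarded; repeated
  instruction requests for one junction merge into a single segment from
  the earliest request; segments are split around exclusion intervals so
  no window overlaps removed data.

## Known limitations

* The 80/20 scheme is included for comparability, but only L5O4T supports
  generalization claims across people.
* The fundamental-period feature is noise-sensitive by construction
  (minimum inter-peak interval); treat it as a descriptor, not a cadence
  estimate.
* The SST gate is uninformative on broadband noise (scores saturate);
  artifact detection therefore rests primarily on the amplitude rule,
  which is exactly what the 10 m/s² threshold encodes.
* Saccade head-compensation uses a fixed linear calibration
  (units-per-degree); real scene cameras have lens distortion the linear
  map ignores. Setting the calibration to zero recovers uncompensated
  amplitudes.
* Synthetic validation bounds what can be claimed: passing tests show the
  pipeline is correct and honest, not that real familiar/unfamiliar
  walkers are separable at any particular accuracy.

## A minimal session

```{r example, eval = FALSE}
library(wayfam)

# a cohort with a contrast planted in yaw dynamics only
out <- run_pipeline(yaw_only_effect_config(ratio = 2),
                    n_participants = 10, seed = 1)
out$experiment$summary
generics::tidy(out$experiment$importance[[1]])

# and a null cohort, which must classify at chance
null_out <- run_pipeline(null_effect_config(), n_participants = 10, seed = 1)
null_out$experiment$summary
```
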