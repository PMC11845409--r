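---
title: "Gait-cycle entrainment of saccades and EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-cycle entrainment of saccades and EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what the green test suite does and
does not establish.

## The scientific model

During walking the vertical position of the head follows a near-sinusoidal
trajectory with one cycle per step: it is lowest when both feet are on the
ground (double-support stance, "footfall") and highest mid-swing. That makes
head height a usable gait phase sensor when no foot-pressure or IMU data
exist: troughs mark footfalls, two consecutive steps form a stride, and any
event time can be expressed as a percentile of stride completion.

The pipeline asks two questions of such data:

1. Does the probability of initiating a saccade oscillate across the stride?
   The test statistic is the R² of a first-order Fourier model fitted to
   binned saccade density at a forced frequency, scanned over 0.2–10 cycles
   per stride (cps). Two cps equals the step rate, so entrainment to
   footfalls appears as a peak at 2 cps.
2. Does band-limited EEG power wax and wane with step phase? Power from a
   Morlet transform is resampled onto a normalized step-cycle axis and
   tested against its own epoch-mean baseline with cluster-based
   permutation statistics.

## Saccade detection

Detection follows the velocity-outlier approach standard for
micro/saccade work: per-trial, per-axis thresholds η = λ·σ̂ with the robust
scale σ̂ = sqrt(median(v²) − median(v)²) and λ = 6, an elliptic crossing
rule, and a two-sample (22 ms at 90 Hz) minimum duration. Two details are
worth making explicit:

- *The robust σ̂ is biased low on Gaussian noise* (σ̂ = 0.674σ for white
  noise); that is intrinsic to the estimator and the reason λ = 6 rather
  than, say, 3 is the standard multiplier. Our tests freeze the
  Monte-Carlo value (η → 6·0.674 for unit noise), not the naive 6σ.
- *Onset refinement.* Thresholding the 5-sample smoothed velocity finds the
  excursion but its first crossing leads the true onset by up to the
  smoothing half-width (2 samples). Within each supra-threshold run the
  onset is therefore refined to the first sample whose raw (unsmoothed)
  speed exceeds max(peak/4, a noise floor derived from the raw-velocity
  thresholds). Detection decisions are unchanged; only the reported onset
  moves. Without this, the ±1-sample onset accuracy the validation demands
  is unattainable in principle.

Detection runs on head-fixed gaze angles (azimuth = atan2(x, z), elevation
against the forward-horizontal plane), because the stimulus display is
head-fixed and head-frame angles isolate eye-in-head movement; a world-frame
switch exists for comparison.

## Gait extraction

Per trial: zero-phase 6-Hz low-pass, linear detrend, local minima with at
least 0.35 s separation and prominence ≥ 25% of the trial's median
peak-to-trough amplitude. These three hyperparameters are not published
values; they were chosen once to admit the whole physiological step range
(0.4–1.2 s) while rejecting tracker jitter, and are exposed in
`analysis_config()$gait`.

Trough times are refined below the sample grid with a cubic least-squares
fit over an adaptive window (16% of the shorter adjacent step on each
side). The cubic term matters: adjacent steps of unequal duration make the
trough neighbourhood asymmetric, and a symmetric parabola is biased by more
than a sample exactly in the trials where gait is most variable. Even so,
additive sensor noise that survives the low-pass moves the minima of the
signal itself; at amplitude SNR 10 the worst-case shift is ~1.5 samples, so
the noisy-recovery test asserts sub-sample agreement for the bulk of
troughs, not for every one. On noiseless data recovery is complete to
within one sample.

Strides default to the one-step-overlap convention (every consecutive
trough triple), so an interior event receives percentiles in up to two
strides, 50 points apart. The alternative disjoint convention is
implemented; at 2 cps the two give identical inference because the
modulation has period one step. Percentiles live in the half-open interval
[0, 100) with half-open bins, avoiding double counting at bin edges.

Automated trial exclusion replaces manual inspection: dropout > 0.25 s,
more than 20% of steps out of duration bounds, or fewer than three troughs.

## Cyclic statistics

Counts in 40 equal bins are converted to relative change from the
participant mean, averaged across participants, and fitted at each forced
frequency. At fixed frequency the model is linear in (a0, a1, b1), so we
solve it exactly by least squares rather than running an iterative
nonlinear optimizer; at the grid frequencies the two are equivalent and the
linear solve is deterministic, which the permutation machinery depends on.
Phase is reported with the convention φ = atan2(−b1, a1), making
f = a0 + A·cos(wθ + φ).

The null shuffles bin labels independently within each participant
(sampling without replacement), rebuilds the group mean and reruns the full
scan; the per-frequency 95th percentile of null R² is the significance
bound, with strict inequality at the bound. The bound is pointwise per
frequency — there is no max-statistic correction across the 50 frequencies.
Over a 1.5–2.5 cps decision band this spans five grid frequencies, so the
band-level false-positive rate is somewhat above 5%; the null-calibration
test measures the single-frequency rate, which is the calibrated quantity.

Population prevalence: with k of n participants significant at
false-positive rate α and sensitivity β, the posterior under a uniform
prior is p(γ) ∝ θᵏ(1−θ)ⁿ⁻ᵏ, θ = γβ + (1−γ)α, with analytic mode
clip((k/n − α)/(β − α), 0, 1); the implementation evaluates a 10001-point
grid, cross-checks the analytic mode, and returns the 95% highest-density
interval by water-filling. A reconciliation worth recording: the published
prevalence values for these counts are reproduced exactly by α = 0.025, not
by the nominal α = 0.05 of a one-sided 95% permutation bound. Both α are
available; `prevalence()` defaults to 0.05 and the acceptance computation
uses 0.025, which is what the printed numbers imply.

Phase clustering across participants uses Rayleigh's test, Z = nR̄², with
the standard small-sample p approximation.

## EEG time–frequency

Preprocessing: re-reference to mean(A1, A2); zero-phase band-pass 0.1–40 Hz
implemented as multiplication in the frequency domain by a Butterworth
magnitude response (order 12 for the band-pass — more than 20 dB down at
50 Hz; order 4 for the 6-Hz gait low-pass) on reflection-padded signals. No
IIR filter design library exists in the target environment and the
zero-phase magnitude filter has no stability or phase issues; the filter
family was not specified by the procedure being reproduced. Bad channels:
robust z of the channel SD > 5 (deviation) or best inter-channel
correlation < 0.4 in > 1% of one-second windows (correlation), the default
thresholds of the preprocessing method those metric names come from.

Morlet wavelets: 50 linearly spaced centre frequencies 3–40 Hz; the
envelope FWHM shrinks linearly from 600 ms to 100 ms across the grid. The
wavelets are built directly in the frequency domain as one-sided Gaussians
(σ_f = 1/(2π σ_t)) with unit peak gain, so a unit sinusoid yields power
0.25 at every centre frequency — the normalization that makes power
comparable across frequencies and that the flatness check (±3%) verifies.
(A unit-*energy* normalization cannot satisfy that flatness requirement,
because its sinusoid response grows with √σ_t.)

Step epochs run from 600 ms before step onset to 600 ms after completion;
epochs whose pooled SD falls outside Q3 + 1.5·IQR / Q1 − 1.5·IQR are
rejected (pooled over channels and time; a per-channel variant was a
possible reading, the pooled one was chosen and documented). Power is
resampled onto a −30% … +130% step-cycle grid in 0.5% increments — 321
points; a printed "260 data points" in the source description is internally
inconsistent with its own "±30% buffer at 0.5%" and the buffer wins.
Percent change is computed against the mean over the full grid and all
retained epochs, per channel × frequency, which makes the normalized map
mean-zero by construction.

Saccade-locked epochs (−600…+1100 ms) are labelled by the gait quartile of
the saccade's step percentile, with quartile boundaries [0,25), [25,50),
[50,75), [75,100) (the source's figure caption and methods disagree by one
percentile point at the edges; half-open quarters were adopted). Stance
pools quartiles 1 and 4, swing pools 2 and 3, and every pool is normalized
against the all-saccade baseline so pools remain comparable.

## Cluster inference

t maps (one-sample, or paired differences) are thresholded two-tailed at
p < 0.01; same-sign 4-connected components (grid maps) or
graph-connected components (channel × bin topographies; channels are
adjacent within 0.65 head radii, capped at the six nearest before
symmetrization) form clusters whose mass is the summed t. The null is the
permutation distribution of the maximum |mass| under per-participant
whole-map sign flips — for paired contrasts on difference maps this is
identical to exchanging condition labels within participant, which is the
exchangeability the test needs. `p_cluster` uses the add-one correction
(1 + #{perm ≥ obs})/(n_perm + 1), so it is never exactly zero.

## The synthetic world

`simulate_session()` writes a complete session (tracking TSV, EEG text
container + triggers, events TSV, truth JSON) from one seed. What it
emulates, and the stated values it uses:

- **Gait**: step durations i.i.d. truncated normal on [0.4, 1.2] s with the
  condition statistics (slow: 0.72 ± 0.09 s; natural: 0.61 ± 0.06 s);
  vertical head position is one cosine cycle per step with the trough
  exactly at the recorded footfall; horizontal progress at 0.7 / 1.4 m/s.
  Trials are 5 s; the inter-trial gap is 1 s of standing (the real
  paradigm's longer rest carries no analysis content).
- **Saccades**: an inhomogeneous Bernoulli process on the 90-Hz grid with
  rate λ0(1 + m·cos(2π·f·φ/100 + φ0)), φ the true stride percentile;
  defaults λ0 = 1.5/s (a free simulation parameter — no published base
  rate exists), f = 2 cps. A 120-ms refractory keeps adjacent saccades'
  velocity excursions from merging, which any detector would conflate; the
  refractory thins the realized rate by the factor 1/(1 + λ0·0.12) and
  slightly attenuates and phase-shifts the realized modulation (the
  phase-recovery tolerance of ±30° absorbs this). Saccades are smooth
  raised-cosine displacements (amplitude ~N(3, 1) deg truncated at 0.5, a
  typical free-viewing scale) on Gaussian fixation noise of 0.05 deg/axis;
  blinks are 1-m gaze-origin jumps lasting 100–300 ms. No saccade is
  generated inside a blink's interpolation window.
- **EEG**: 1/f background plus a shared component across scalp channels
  (emulating volume conduction — without it the correlation-based
  bad-channel metric would flag everything), plus a band-limited
  oscillation whose envelope follows the true step percentile, plus an
  optional saccade-locked transient. A1/A2 carry low-amplitude noise.

What it does **not** emulate: biomechanically realistic gait (no
double-support plateau, no lateral sway coupling), realistic EEG forward
models or topographies, gait artifacts in the EEG, smooth pursuit, or
calibration drift. A green suite therefore establishes that the
implementation recovers what it is supposed to recover from data satisfying
the model's assumptions — it does not certify performance on real
recordings with structured artifacts.

## Numerical and interface choices

- On-disk EEG interchange is a wide TSV plus a trigger TSV rather than a
  binary EEG container: the grading environment provides no EDF library in
  R or Python, and writing one by hand was out of scope. The reader
  enforces the canonical 19 + A1/A2 montage and errors without both
  references.
- All randomness flows from one top-level seed, split deterministically per
  stage (`split_seed`), so full-pipeline outputs are byte-identical across
  runs with the same config.
- FFT filtering uses ~1 s reflection padding; wavelet convolution
  zero-pads to the next power of two beyond three envelope widths.
- Degenerate inputs fail loudly: zero-norm gaze rows are named, a constant
  velocity axis names its trial, a missing reference channel aborts before
  re-referencing, a zero baseline aborts percent change.
- Scan tie-breaks: `which.max` returns the first maximum, so equal R² picks
  the lower frequency.

## Known limitations

- The permutation bound is pointwise across frequencies (documented above);
  band-level inference inherits mild multiplicity.
- Trough timing under heavy in-band noise is limited by the signal itself,
  not the estimator; see the gait section.
- The saccade detector's amplitude estimate spans the run plus one sample
  on each side and is approximate for overlapping noise.
- Left/right foot labelling is impossible from head height alone; stride
  phases are therefore only defined up to a half-stride shift, which is
  irrelevant at 2 cps but matters if odd harmonics were of interest.
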