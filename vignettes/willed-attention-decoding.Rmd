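---
title: "Decoding willed covert attention from alpha oscillations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding willed covert attention from alpha oscillations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(willdecode)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish
about real recordings.

## The phenomenon and the measurement model

Covert visuospatial attention suppresses posterior alpha-band activity over
the hemisphere contralateral to the attended hemifield. In a *willed*
attention paradigm the observer chooses both where and when to attend, and
the only overt marker of the decision is a self-paced left/right button
press that ends the trial. The analysis therefore time-locks backwards from
the press and asks, at every timepoint, whether a classifier can read the
chosen side out of the spatial pattern of alpha power — the moment decoding
rises above chance bounds the latency of the covert shift.

Two confounds shape the design. The flickering stimulus arrays drive 4 and
6 Hz responses (and 8/12 Hz harmonics) over occipital cortex, so the alpha
band is restricted to 9–11 Hz. And the response hand is always the right
hand, so motor preparation drives a central mu rhythm (~10 Hz) that is
*identical* for attend-left and attend-right trials; decoding a central
electrode set separately checks that mu cannot explain posterior decoding.

## The synthetic session generator

`sim_config()` + `sample_behavior()` + `synthesize_session()` produce
continuous 64-channel recordings with exact ground truth. The generator is
a linear forward model: each source is a (scalp topography, waveform) pair,
and the recording is the mixed sum. Topographies are Gaussians in
great-circle distance on the unit sphere (`build_topography()`), a smooth
stand-in for volume conduction.

* **Behavior.** Attend sides are i.i.d. fair coin flips (so there is no
  sequential structure to exploit — `sequential_dependence_test()` checks
  this on the generated tables). Trial latencies are lognormal, moment-
  matched to the configured mean/sd (defaults 3.9 s / 3.7 s) and truncated
  to [1.2, 20] s by redrawing: a positive, right-skewed stand-in,
  constrained only through its mean and spread. The attention onset
  precedes the press by a normal lead (mean 1.5 s, sd 0.4 s), floored at
  1 s — one full expansion cycle of sustained attention — and clipped so it
  always falls strictly inside the trial.
* **Alpha.** Two 10 Hz sources at PO7/PO8 (spread 0.7 rad). From attention
  onset to the press, the source contralateral to the attended side is
  multiplied by `1 - lateralization_fraction`; transitions use 100 ms
  raised-cosine ramps to avoid broadband clicks.
* **Mu.** One source at C3 (the right-hand motor region) ramping linearly
  over the 500 ms before every press and decaying 200 ms after it —
  deliberately identical across attend sides, hence non-informative.
* **Flicker.** Sinusoids at 4 and 6 Hz plus half-amplitude first harmonics
  at O1/O2 while the array is on, with the 4-vs-6 side assignment
  re-randomized per trial. Square-wave luminance is not modelled: only the
  spectral exclusion from 9–11 Hz matters for these analyses.
* **Background.** Sixteen-to-twelve independent 1/f sources (spectrally
  shaped Gaussian noise, exponent `one_over_f_exponent`) spread over the
  scalp, rescaled so `noise_amp` is the average sensor-level standard
  deviation (default 8 µV). This gives IRASA a true fractal component to
  separate. The FT9/FT10 eye-proxy and TP9/TP10 reference sites receive
  15% of the cortical background: these cap-edge channels carry little
  cortical signal in real recordings (quietness is why mastoid-adjacent
  sites serve as references), keeping the 20 µV eye-movement criterion
  responsive to ocular transients rather than ongoing EEG and keeping
  re-referencing from injecting background into every channel.
* **Blinks.** Stereotyped 300 ms biphasic transients, 120 µV peak at
  Fp1/Fp2, decaying posteriorly, at `blink_rate` per minute. They exceed
  the 100 µV rejection threshold by construction, so enabling them is the
  test of the artifact pipeline; ICA-style blink removal is out of scope
  and the generator's `blink_rate = 0` plays that role in analyses.

What the generator does **not** emulate: non-stationary alpha amplitude
dynamics, heterogeneous subject anatomy and electrode impedances, muscle
and line noise, genuine saccade dynamics, or any nonlinearity of volume
conduction. Passing tests on this model therefore demonstrate that the
*pipeline* is correct and calibrated — not that real data would yield the
same effect sizes.

## Preprocessing choices

The band edges (0.05–50 Hz) are realized as a cascade of a 2nd-order
Butterworth high-pass at 0.05 Hz and a 4th-order low-pass at 50 Hz, each
applied forward-backward (zero phase). A single band-pass with a normalized
low edge of 1e-4 at 1000 samples/s is numerically ill-conditioned; the
cascade has the same passband and avoids latency bias in response-locked
analyses. Downsampling uses a zero-phase 64-tap FIR anti-alias filter with
cutoff at 0.8 × the target Nyquist, then decimation; event indices map as
`(i - 1) %/% q + 1`.

The peak-to-peak rejector rounds 100 ms to 25 samples and 50 ms to 12
samples (floor) at 250 Hz and flushes a final window to the epoch end so
coverage is complete. It runs on all non-reference channels by default
(configurable, and restricted to the analysis channels in the replicated
desk-scale studies below). Rejection only ever removes trials: the kept
mask is cumulative, so the 100 µV and 20 µV screens commute.

## Time–frequency, Laplacian, IRASA

Alpha power uses a Hann taper of 3 cycles per frequency (f ∈ {9, 10, 11}),
centred on each point of a 20 ms grid aligned to the lock event; the
Fourier coefficient is evaluated directly at f and normalized so a unit
sinusoid yields power 1. Timepoints whose widest (9 Hz ≈ 333 ms) window
leaves the epoch are `NA`, never zero. Power is averaged over the three
frequencies at the trial level before any statistics.

The surface Laplacian is a spherical-spline current source density with
order m = 4, 50 Legendre terms, and ridge regularization 1e-5 (all
configurable); the output is the negative surface Laplacian of the fitted
spline at the electrodes, in spline units per steradian on the unit sphere
(a fixed positive scale of µV/cm² for a given head radius — topography
figures use normalized colour scales, so absolute calibration is not
needed). The transform is precomputed as a matrix, hence exactly linear and
reference-free.

IRASA resamples the signal by factors h = 1.10…1.90 (step 0.05, rational
p/20) and by 1/h, computes Welch PSDs (Hann, half-overlapping segments, 4 s
default) on the original grid, geometric-means each pair, and takes the
median across factors as the fractal component; `oscillatory = total −
fractal` holds exactly by construction. The fractal log–log slope is
recovered by least squares over 2–30 Hz.

## Decoding and inference

The classifier is a soft-margin linear SVM with cost 1 on fold-averaged
exemplars: trials of each (equalized) class are partitioned into three
shuffled folds, averaged into one exemplar per class per fold, standardized
by training-fold statistics, and the held-out fold's two exemplars are
tested; ten re-randomized iterations are averaged. Averaging into exemplars
boosts signal-to-noise and makes the per-fit problem tiny, so the solver is
a small in-package SMO (a few microseconds per fit); `e1071::svm` (libsvm)
serves as an independent cross-check in the test suite. A test exemplar
exactly on the decision boundary counts as incorrect — a conservative,
deterministic tie-break that also defines the degenerate all-constant case.
Fold partitions are drawn from a single shuffle of the pooled trials, so
label coding does not change how the random stream is consumed.

The fold-remainder (n mod 3) is dropped within each iteration.
Equalization is drawn once per subject per analysis, seed-controlled.
Smoothing (5-point moving average, shrinking at the edges) is display-only
and never precedes statistics.

Cluster inference: one-sample t of subject accuracies against 0.5 at every
timepoint (one-sided — below-chance decoding is not of interest), clusters
are maximal runs above the pointwise critical value, and each permutation
of the Monte-Carlo null re-decodes every subject with i.i.d. uniform labels
and records the maximum cluster mass. Cluster p =
`(1 + #{null ≥ mass}) / (1 + n_permutations)`, which floors at
`1/(1+n)` and controls the family-wise rate. With few subjects and
coarsely quantized accuracies, zero-variance timepoints occur; their ±∞ t
sentinel is capped at t = 100 (larger than any achievable finite t at
these sizes) on both the observed and null sides before masses are formed,
which keeps infinite masses comparable without affecting any finite t.
Weight maps multiply each fold's weight vector by the trial-feature
covariance (1e-6 diagonal shrinkage when near-singular), the standard
activation-pattern correction that makes channel contributions
interpretable.

The asymmetry test averages alpha power over the posterior-left minus
posterior-right channels (midline excluded) per trial and compares attend
sides with a two-sided Welch t, the variant appropriate for pooled trial
bins of unequal size and variance. The lag-1 choice dependence is an
in-package IRLS logistic regression with a Wald test; complete separation
(all choices identical) is reported as an error, and a perfectly
alternating sequence yields the expected large negative slope with an
infinite standard error.

## Desk-scale study sizes

The replicated studies that calibrate and power-check the pipeline run at a
reduced problem size chosen once: 4 subjects × 60 trials, synthesized
directly at 250 samples/s, lognormal latencies with mean 2.2 s (sd 0.6 s),
attention lead mean 1.5 s (sd 0.3 s), blinks disabled, 200 Monte-Carlo
permutations, and 2 decoding iterations (1 in the null-calibration study,
whose validity rests only on observed and null pipelines sharing all
parameters). The calibration study uses a −2000..500 ms response-locked
window; the recovery study uses −3000..500 ms so that its baseline window
(−3000..−2500 ms) lies entirely before the earliest possible attention
onset. Full-scale defaults (20 subjects, ~479 trials, 1000 samples/s,
−4000..1400 ms windows, 10 iterations) remain in `sim_config()` and
`epoch_events()`.

```{r studies}
calibration_study(n_replicates = 200, seed = 1)   # FWER under the global null
recovery_study(n_replicates = 50, seed = 1)       # planted-effect recovery
dissociation_study(n_replicates = 50, seed = 1)   # posterior vs central
```

## Known limitations

* The generator's alpha is a deterministic sinusoid under an envelope;
  real alpha is bursty and amplitude-modulated, so real-data decoding
  accuracies will be lower at matched effect sizes.
* The 20 ms decoding grid follows the stated increment; applied to the
  stated epoch windows this gives 251 and 271 grid points (stimulus- and
  response-locked), and the grid size is logged rather than forced to any
  other count.
* The EDF writer covers the 16-bit single-rate case this package emits; it
  is not a general EDF implementation.
* Cluster-level inference controls the family-wise rate across time within
  one analysis, not across channel sets or locks.
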