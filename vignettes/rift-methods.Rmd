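---
title: "Rapid invisible frequency tagging: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid invisible frequency tagging: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Rapid invisible frequency tagging (RIFT) modulates the luminance or
contrast of a visual stimulus sinusoidally at around 60 Hz — fast enough
that observers cannot see the flicker, slow enough that visual cortex
still produces a measurable steady-state response at the tagging
frequency in MEG. `rifttag` implements the computational chain such a
study needs: generating the tagging waveforms, reconstructing the
reference signal that was actually displayed, spectral analysis with
inter-trial coherence (ITC) and brain-to-tagging (phase-corrected)
coherence, disentangling two simultaneous stimuli tagged at orthogonal
phases, equivalent-current-dipole (ECD) source modelling in a spherical
conductor, and the hierarchical Bayesian behavioural analysis that
certifies the tagging's invisibility. A fully seeded synthetic MEG and
behaviour generator provides ground truth for end-to-end validation.

## Tagging waveforms

Four protocols modulate the white and black bands of a grating with
`s(t) = sin(2*pi*f*t + phi)` at the projector frame rate (default
1440 frames/s; the luminance is held constant within a frame):

| Type | white band        | black band        | character |
|------|-------------------|-------------------|-----------|
| 1    | `0.5 + 0.5 s`     | `0`               | full-amplitude luminance |
| 2    | `0.75 + 0.25 s`   | `0`               | half-amplitude luminance |
| 3    | `0.75 + 0.25 s`   | `0.25 + 0.25 s`   | additive luminance, constant contrast |
| 4    | `0.75 + 0.25 s`   | `0.25 - 0.25 s`   | contrast tagging, constant mean luminance |

Over whole cycles, type 1 averages to mid-grey (50%) while types 2–4
keep the white bands at 75%. These means are exact on a frame grid that
tiles whole cycles (60 Hz at 1440 frames/s: 24 frames per cycle).

## The corrected tagging signal

Coherence against the tagging requires knowing what was *displayed*, not
what was generated. `reconstruct_corrected_tag()` re-aligns the stored
sinusoid to the stimulus onset detected on the light-sensor trace (first
sample above half the trace maximum) and inserts a delay at every
projector flip whose lateness exceeds 1 ms, quantized to whole samples
(ties rounding down; at 600 Hz one sample is 1.67 ms, so a two-frame
stall of 1.39 ms is represented by a one-sample delay, an error below
one sample by construction). The flip log records the re-anchored
schedule, so each stall appears exactly once.

The simulator's light sensor is idealized and monotone: after onset it
emits the pedestal-mapped modulation `0.75 + 0.25 s(t)` and is zero
before. The pedestal guarantees that every post-onset sample exceeds
half the trace maximum, so half-maximum onset detection finds the true
onset sample exactly for any tagging phase. Real photodiodes are
noisier and possibly nonlinear; the package models the best case the
correction procedure assumes.

## Spectral estimators

Spectra use a 1 s analysis window 0.2–1.2 s after onset with a boxcar
(flat) taper — 1 Hz resolution and no smearing of the 60 Hz line into
its neighbours, at the cost of higher variance than a multitaper
estimate. With `F` the sensor and `G` the tagging Fourier coefficient:

* power = mean over trials of `|F|^2`;
* ITC = `|mean(F/|F|)|` over trials — consistency of the *absolute*
  phase, which presumes a fixed stimulation phase;
* brain-to-tagging coherence =
  `|sum F conj(G)| / sqrt(sum |F|^2 sum |G|^2)` — consistency of the
  phase *difference*, immune to trial-varying stimulation phase and to
  any constant apparatus delay.

Whether the original analysis weighted by magnitude or used phase-only
averaging is not determinable from prose alone; both are implemented
(`tag_coherence(method = "weighted")` is the default,
`"phase_only"` is the ITC of phase-corrected coefficients) and agree at
high SNR. The SNR statistic compares the value at the frequency of
interest with the mean over `[foi-5, foi-2] + [foi+2, foi+5]` Hz
(8 bins at 1 Hz spacing) in decibels, `10*log10(x/mean(neighbours))`.

A statistical caveat that matters for testing: at bins with no phase
locking, ITC's across-trial resultant is a single Rayleigh-distributed
draw, so the *single-run* ITC-based SNR at a null frequency scatters
around 0 dB with a spread of roughly 1 dB (and a small negative median
from the log transform) even with hundreds of trials. The package's
acceptance checks therefore evaluate the null-regime band on a
grand-average ITC spectrum over 24 independent runs, where the
numerator averages independent draws and the statistic concentrates
within a few tenths of a dB of zero. Single-run checks of the same
regime use correspondingly wider bands.

## Phase tagging

Phase correction divides each trial's coefficients by the unit-magnitude
tagging coefficient, `F_corr = F conj(G)/|G|` — equal to the division
`F/G` up to a positive per-trial scale, and magnitude-preserving.
Projection onto a candidate phase is
`A = Re{conj(F) e^{i phi}}`; summed squared projections over channels
(global field power) as a function of a 32-point phase grid (steps of
pi/16) peak at the participant's tagging-to-brain lag. Because
`A(phi + pi) = -A(phi)`, the profile is pi-periodic: the peak is
reported in `[0, pi)`, and the induced joint sign flip of the projected
topographies flips fitted dipole *moments*, never positions, so the
left/right laterality analysis is unaffected. No interpolation is done
between grid points; recovery is accurate to the grid step.

For two stimuli tagged at the same frequency with a 90-degree phase
offset, the correction is anchored to the left stimulus's tagging
signal (a convention; the design constraint then places the right
stimulus at +90 degrees). Projecting trial-averaged corrected
coefficients at the peak lag isolates the left-stimulus response;
projecting at the 90-degree-shifted lag isolates the right. Averaging
before projecting and projecting before averaging are algebraically
identical by linearity. Crucially, the lag must be estimated on
*independent single-stimulus* data: in the two-stimulus mixture the two
orthogonal responses flatten the phase profile, so its argmax no longer
identifies the lag.

## Source modelling

The forward model is a current dipole in a homogeneous conducting
sphere, evaluated as the radial field component at radial magnetometers:
`B_r = -(Q x r_q) . r_hat / |r - r_q|^3` in arbitrary units. The radial
component is independent of volume currents, dipoles at the center and
radial moments are silent, and the field is linear in the moment — the
properties the fitting and the laterality logic rely on. This replaces
subject-specific single-shell conduction: all positions live in a
synthetic head frame (mm; +x right, -y posterior), not true MNI space,
but the x > 0 = right-hemisphere convention is preserved. Consequently,
position *differences* (the dx contrast) are meaningful within the
simulation, while absolute coordinates are not comparable to
template-brain values.

`fit_ecd()` searches over position with Nelder-Mead (relative tolerance
1e-12) from the fixed calcarine start `(0, -88, -9)` mm plus five
deterministic offset restarts, solving the tangential moment linearly at
each candidate; the moment's radial dimension is excluded because it is
unobservable. Explained variance is `1 - RSS/||topo||^2`. Noise-free
round trips recover positions to well under a millimetre. The
kernel-density difference map uses an isotropic Gaussian kernel
(s.d. 15 mm) on a 5 mm grid by default (10 mm in the demonstration
pipeline to keep its output small), each density discretely normalized
before subtraction.

## Behavioural inference

The AXB discrimination data are modelled as a Bernoulli hierarchical
logistic regression: response side against correct side coded
-0.5/+0.5, intercept and sensitivity both subject-random. Trials are
aggregated exactly into per-subject binomial cells, which leaves the
likelihood unchanged and makes MCMC (JAGS, 2 chains, checked with the
Gelman–Rubin r-hat, flagged above 1.01) fast enough for
simulation-based sensitivity analysis. With this coding a population at
accuracy `p` has sensitivity `beta = 2*logit(p)`. Priors are
zero-centered normals with scale 2.5 on coefficients (the standard
weakly-informative logistic scale) and half-normal(0, 1) on
random-effect s.d.s; a tiny lower truncation (1e-3) on the s.d.s keeps
precisions finite on degenerate data. The exact prior scales of the
original analysis tooling are not recoverable, so Bayes factors are
expected to reproduce in order of magnitude rather than digit for digit.

Evidence is summarized with the Savage–Dickey density ratio:
`BF01 = p(beta = 0 | data) / p(beta = 0)`, the posterior density
estimated by a Gaussian KDE over the draws. When the posterior mass
sits far from zero the KDE at zero underflows; BF01 is then reported at
a numerical floor (1e-6) with a flag. Timeout trials (default rate
0.023, the observed median) are excluded everywhere; subject-condition
cells with at most one responded trial are dropped from the descriptive
accuracy table but kept in the model.

The sensitivity analysis simulates response tables on an accuracy grid
(0.40–0.60 in steps of 0.01) with truncated-normal between-subject
spread (the distributional form of the original spread is unstated;
normal-with-given-s.d. is the minimal reading, default s.d. 0.05),
fits each, and summarizes median and IQR of BF01 per level plus a
quadratic fit to median `log2(BF01)` — log2 for interpretability of
evidence doublings. 300 simulations per level reproduce the original
design; the test suite and demonstration use 10–20 per level, which is
enough for the curve's shape (peak at chance, flanks below 1/3) at a
fraction of the cost. Because adjacent grid levels around 0.5 differ by
far less than the sampling spread of a 20-simulation median, the
curve's peak location is assessed within ±2 grid steps of chance and
via the quadratic vertex, not as an exact argmax.

## The synthetic generator and what it does not emulate

`simulate_epochs()` drives occipital dipole sources with the *displayed*
frame-held modulation (including injected projector stalls), maps them
through the spherical forward model, and adds: per-channel 1/f
background (spectrally shaped white noise, exponent 1), a spatially
coherent ~10 Hz alpha component weighted towards posterior sensors with
random phase and slow amplitude modulation per trial, common-mode 50 Hz
line noise with random phase per trial, and white sensor noise. Epochs
span [-0.4, 1.2) s at 600 Hz; behavioural defaults are 12 subjects and
50 trials per block — the scale of the study being emulated. The
default source amplitude (200) and noise amplitudes (1/f 1, alpha 2,
line 1, white 0.3) were calibrated once so that posterior-sensor
coherence SNR at 60 Hz lands near 5–7 dB with ~100 trials, the scale
such recordings produce, and are not tuned per analysis.

Deliberately not emulated: realistic anatomy and single-shell/BEM
conduction, axial gradiometry, eye/cardiac artifacts, head motion,
nonstationary noise, stimulus-offset transients, and the perceptual
side of the task (behaviour is generated directly from an assumed
accuracy, not from the MEG signal). Passing tests therefore show that
the *analysis chain* is correct and well-calibrated under its stated
assumptions — not that real recordings satisfy those assumptions.

## Problem sizes and determinism

The demonstration pipeline (`run_demo()`) uses 32 channels, 60–80
trials per condition, 12 simulated participants, and reduced MCMC
settings (2 chains of 800 draws after 500 warm-up); the acceptance
script uses cohorts of 12–24 runs for spectral grand averages, 20
participants for laterality, 100 dipole round trips, and 10–20
simulations per sensitivity level. Every stochastic stage receives a
seed derived from the master seed by a documented counter scheme
(`derive_seed()`), chains carry explicit RNG seeds, and reruns of any
stage are byte-identical in their CSV/JSON outputs.
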