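# rifttag

Simulation and analysis tools for **rapid invisible frequency tagging
(RIFT)** studies with MEG.

RIFT presents visual stimuli whose luminance or contrast oscillates
sinusoidally at ~60 Hz using a high-refresh-rate projector — too fast to
see, but strong enough to drive a steady-state response in visual cortex
at the tagging frequency. Researchers using the technique face four
computational problems, and this package implements all of them on a
common, fully seeded synthetic data generator:

1. **Tagging waveforms** — the four canonical protocols (full/half
   luminance, additive luminance, contrast tagging) evaluated per
   projector frame, plus reconstruction of the *corrected tagging
   signal*: the stored sinusoid re-aligned to the light-sensor onset and
   delayed at every projector flip missed by more than 1 ms.
2. **Spectral readout** — boxcar-taper Fourier coefficients over a 1 s
   window (1 Hz resolution), power, inter-trial coherence (ITC),
   brain-to-tagging (phase-corrected) coherence
   `|Σ F·conj(G)| / sqrt(Σ|F|² Σ|G|²)`, and the SNR statistic
   `10·log10(x(foi) / mean(x[foi±2..5 Hz]))` in dB. ITC requires a fixed
   stimulation phase; phase-corrected coherence does not.
3. **Phase tagging** — correcting sensor coefficients by the displayed
   tagging phase (`F·conj(G)/|G|`), projecting onto a 32-point phase
   grid to estimate each participant's tagging-to-brain lag from the
   global field power profile, and splitting two-stimulus
   orthogonal-phase data into per-stimulus topographies; equivalent
   current dipole (ECD) fits in a spherical conductor then test the
   contralateral-hemisphere prediction (left stimulus → x > 0).
4. **Behavioural invisibility** — hierarchical Bayesian logistic
   regression of AXB discrimination responses (subject-random intercept
   and sensitivity, Savage–Dickey BF01 on the sensitivity) with a
   simulation-based sensitivity analysis over true accuracies 0.40–0.60.

## Worked example

Estimate a simulated participant's tagging-to-brain lag from
single-stimulus random-phase data, then disentangle a two-stimulus
orthogonal-phase run:

```r
library(rifttag)

array <- make_sensor_array(32)                      # radial sensors, helmet cap
model <- head_model(array)                          # spherical conductor

# single central stimulus, random tagging phase per trial, injected lag 0.7 rad
solo <- simulate_epochs(default_sources(1, 200, extra_phase = 0.7),
                        array, 60, noise_config(), "random", seed = 1)
spec <- fft_boxcar(solo)                            # corrected-tag coefficients included
prof <- lag_profile(colMeans(phase_correct(spec, 60)))
prof$peak_phase
#> [1] 0.5890486                                     # 3*pi/16, one grid step from 0.7

# two stimuli, same 60 Hz frequency, right stimulus at +90 degrees
two <- simulate_epochs(default_sources(2, 200, extra_phase = 0.7),
                       array, 80, noise_config(), "two_stim_orthogonal", seed = 2)
topos <- disentangle_two_stim(fft_boxcar(two), prof$peak_phase)
fit_ecd(topos$topo_at_peak, model)$position         # left stimulus: right hemisphere
#> [1]  18.451537 -87.339713  -7.107589
fit_ecd(topos$topo_at_peak_plus_90, model)$position # right stimulus: left hemisphere
#> [1] -18.47806 -87.41574  -6.02095
```

The fitted x-coordinates land at roughly ±20 mm — the ground-truth
source positions — on opposite sides of the head midline, which is the
critical signature that orthogonal-phase tagging cleanly separates the
two stimuli.

The numbered scripts under `analysis/` run the four analysis strands
end-to-end on synthetic data and write their tables under `results/`.
For example `analysis/03_phase_correction_snr.R` prints:

```
Tagging SNR (dB at 60 Hz) by phase regime and analysis method:
 phase_mode snr_itc_db snr_phase_corrected_db
      fixed      6.861                   7.06
     random      0.233                   6.53
```

— with randomized tagging phases, ITC collapses to the noise floor
while the phase-corrected coherence keeps its SNR, the property that
makes phase tagging possible at all. `analysis/05_behaviour_invisibility.R`
fits the behavioural model to chance-level simulated observers
(BF01 ≈ 9–10 in favour of random guessing per block) and prints the
sensitivity curve showing BF01 peaking at true accuracy 0.5 and
dropping below 1/3 beyond ±0.05 of chance.

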