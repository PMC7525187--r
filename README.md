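# cardioflow

Video-based contractility analysis for beating cardiomyocyte cultures,
plus the matching multielectrode-array (MEA) metric layer.

Spontaneously beating monolayers of human iPSC-derived cardiomyocytes are
routinely characterized two ways: optically, by how the image texture
deforms as the tissue contracts, and electrically, by extracellular field
potentials. `cardioflow` implements both readouts as a tested pipeline:

* **Optical flow.** Displacement fields d(t, x) between a resting
  reference frame t\* and every other frame are estimated by two-stage
  tile-based block matching: 64-px tiles scored by Euclidean intensity
  distance, a thin-plate-spline fit that interpolates and denoises the
  coarse field, then 32-px tiles searched within ±4 px of the spline
  prediction.
* **Beat dynamics.** The beat pattern D(t) = ⟨|d(t, x)|⟩ₓ is reduced to a
  power spectrum (squared DFT magnitudes); the dominant peak is the beat
  frequency, with harmonics at 2f, 3f, … for pulse-like beats.
* **Convergence mapping.** Convergence = −div d, estimated by central
  differences on the tile grid, separates active contraction from passive
  translation and localizes contractile centers as thresholded local
  maxima of the time-maximum map.
* **MEA metrics.** Spike detection on median-subtracted traces yields beat
  period, field potential duration (FPD), Fridericia-corrected
  FPDc = FPD / T^(1/3), spike amplitude, a beat-period irregularity CV
  with an arrhythmia flag, and baseline-vs-treated drug contrasts.
* **Synthetic scenes.** A generator produces textured videos deformed by
  known Gaussian contraction centers and MEA-like traces with known spike
  times, FPD and alternans, so every stage is testable against analytic
  ground truth.

## Worked example

```r
library(cardioflow)

# a 20 s, 30 fps synthetic monolayer beating at 1 Hz around one center
sp <- scene_spec(image_size = c(128, 128), texture_seed = 7,
                 centers = contraction_center(c(64.5, 64.5),
                                              amplitude = 4, radius = 36),
                 beat_frequency = 1.0, waveform = "half_wave_pulse",
                 frame_rate = 30, duration = 20)
video <- generate_video(sp)

flow  <- compute_flow(video, search_radius = 8)  # picks t* automatically
beats <- beat_pattern(flow)
dom   <- dominant_frequency(power_spectrum(beats))
sprintf("t* = %d, f = %.2f Hz, max D = %.2f px",
        flow$reference_index, dom$frequency, max(beats$D))
#> "t* = 1, f = 1.00 Hz, max D = 1.78 px"

conv  <- convergence_series(flow)
rest  <- which(beats$D <= quantile(beats$D, 0.2))
locate_centers(conv, convergence_threshold(conv, rest), min_separation = 32)
#>    row  col peak_convergence frame
#> 1 64.5 64.5        0.1520288    26
```

The reference frame lands in a rest interval, the dominant spectral peak
recovers the 1 Hz beat exactly (the DFT bin width is 0.05 Hz), the peak
beat-pattern excursion is 1.78 px, and the single contractile center is
called at the true position (64.5, 64.5).

The field-potential layer, on a synthetic 30 s trace beating at 1.04 s
with a 0.35 s FPD and 2 % noise:

```r
tr <- generate_field_potential(fp_spec(duration = 30, beat_period = 1.04,
                                       fpd = 0.35, noise_sd = 2, seed = 5))
compute_beat_metrics(tr)
#> beat_metrics: 28 beats, period 1.040 s, FPD 0.351 s, FPDc 0.346 s,
#>               amplitude 104, CV 0.000
```

`run_contractility()` / `run_fp()` orchestrate full runs with CSV/JSON
artifacts and hash-verified reproducibility; `inst/cli/cardioflow.R` is a
thin command-line wrapper (`simulate-video`, `simulate-fp`, `run-all`,
`fp`).

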