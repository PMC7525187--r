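---
title: "Quantifying cardiomyocyte contractility from video and field potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiomyocyte contractility from video and field potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioflow)
```

## The measurement problem

Cultured human iPSC-derived cardiomyocytes beat spontaneously. Two
complementary readouts quantify that activity without dyes or genetic
reporters:

* **Videomicroscopy.** A beating monolayer deforms the image texture
  periodically. Estimating the displacement field `d(t, x)` of every frame
  relative to a resting reference frame turns a video into a quantitative
  contractility record: its spatial mean magnitude `D(t)` (the *beat
  pattern*) oscillates at the beat rate, its Fourier power spectrum locates
  the beat frequency and its harmonics, and the *convergence*
  (negative divergence) of the field localizes contractile centers.
* **Multielectrode arrays (MEA).** Extracellular field potentials give beat
  period, field potential duration (FPD, an in vitro analogue of the QT
  interval), its rate-corrected value FPDc, spike amplitude, and beat-period
  irregularity -- the standard endpoints for chronotropic and
  pro-arrhythmic drug effects.

`cardioflow` implements both layers plus a synthetic-data module that
generates videos and traces with *known* ground truth, so every stage of
the analysis is verifiable end to end.

## Two-stage block-matching optical flow

A displacement field between a reference frame and a moving frame is
estimated in two passes:

1. **Coarse pass.** The reference frame is divided into overlapping 64-px
   tiles (50 % overlap by default). For each tile, every integer shift
   within a search radius is scored by the Euclidean distance between
   intensity patches, and the minimizing shift is taken. Ties are broken by
   the smallest displacement magnitude, then lexicographically, making
   results bit-reproducible.
2. **Thin-plate-spline smoothing.** One TPS per displacement component is
   fitted to the valid coarse vectors. The spline interpolates and denoises
   the integer-valued matches and can be evaluated anywhere; this is where
   sub-pixel structure enters. Invalid tiles (no in-bounds candidate) are
   excluded from the fit.
3. **Fine pass.** 32-px tiles are matched within a +/- 4 px window centered
   on the rounded spline prediction; the final vector is prediction +
   residual, so displacements far beyond 4 px are still recovered when the
   coarse stage predicts them. On any pair whose true displacement is
   uniform and integer, the two stages collapse to an exhaustive
   single-stage search -- an equivalence the test suite asserts
   vector-for-vector against an independent brute-force matcher.

Matching uses raw intensities, as plain Euclidean block matching does;
whole-frame standardization is available (`normalize = TRUE`) but off by
default. Matching is deliberately integer-only -- no parabolic peak
interpolation -- because the spline already provides the real-valued field
that downstream stages consume.

Parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `tile_size` / `fine_tile` | 64 / 32 px | matching tile widths |
| `step_frac` | 0.5 | tile spacing as fraction of tile (50 % overlap) |
| `search_radius` | 16 px | coarse search extent per component |
| `fine_radius` | 4 px | residual search around the prediction |
| `lambda` | `"gcv"` | TPS smoothing; generalized cross-validation |

The coarse radius bounds the largest recoverable displacement. Monolayer
displacements are small relative to the frame, so a full-frame scan would
buy nothing at quadratic cost; the radius is configurable where scenes are
known to move less (the bundled analyses of 128-px synthetic scenes with
at most 4 px of motion use `search_radius = 8`).

Coordinates are 1-based `(row, col)` pixel positions, R's native matrix
convention; a displacement maps a reference position to the corresponding
moving-frame position.

## Reference frame and beat pattern

The reference frame `t*` must be a frame between contraction cycles where
movement is minimal, i.e. `V(t) >= V(t*)` for all `t`. The motion measure
`V(t)` is the mean coarse-flow displacement magnitude between consecutive
frames -- a cheap single-stage pass with small abutting tiles. Because
matching is integer-valued, `V` quantizes to exactly zero both inside rest
intervals and across the instant of peak contraction (where the velocity
also vanishes); among frames tied at the minimum the selector therefore
prefers the lowest mean match dissimilarity, which is zero only when
consecutive frames are genuinely identical, and takes the earliest frame on
remaining ties. With plain motion values and no scores the rule reduces to
"earliest minimum".

`D(t)` is then the mean over valid tiles of `|d(t, x)|`, with `D(t*) = 0`
exactly by construction. The power spectrum is the squared-magnitude DFT of
the mean-subtracted `D(t)`: mean subtraction prevents the rest-state offset
from leaking into low-frequency bins, and no taper window is applied by
default (beat frequencies of interest sit many bins above DC, and windowing
would trade bin purity for leakage suppression the tests do not need). The
dominant frequency is the bin with maximal power at or above `min_freq`
(default 0.05 Hz, excluding drift); for the non-sinusoidal pulse-like beats
of real monolayers, harmonics appear at integer multiples `2f, 3f, ...`.

## Convergence maps

Passive translation of a cell sheet is invisible to divergence: only
spatial gradients of the field survive. Convergence (`-div d`) is computed
by second-order central differences on the tile grid (one-sided and flagged
at the borders), by default on the TPS-smoothed field so that
integer-matching noise does not dominate the derivative. Units are
displacement per frame interval, *not* per second -- the field is relative
to the reference state rather than a velocity. Contractile centers are
local maxima of the time-maximum convergence map above a threshold
(default: three times the median absolute convergence of resting frames),
greedily pruned to a minimum separation. Time-mean and single-frame
reductions are also provided (`reduce_convergence`), since a map display
may reasonably use any of the three.

## Field-potential metrics

Spikes are detected on the absolute deviation from a running median
(0.5 s window), which removes drift and makes polarity irrelevant. A peak
must exceed half the global maximum deviation -- keeping the smaller, slower
repolarization wave from being miscounted as a beat -- and ten times the
MAD of the deviation, an absolute floor so spike-free noise yields no
detections; detection is scale-invariant, so all timing metrics are
unchanged under voltage rescaling. Beat periods are successive spike-time
differences. Spike amplitude is max minus min voltage within a +/- 25 ms
window. FPD is the delay from spike to the extremum of the Gaussian-
smoothed (8 ms) baseline-subtracted trace, searched from 0.1 s after the
spike to 80 % of the local beat period; a beat whose extremum stays below
5 % of its spike amplitude is flagged undetected. The rate correction is
Fridericia's cube-root rule `FPDc = FPD / T^(1/3)` (period in seconds),
so FPDc = FPD at 1 Hz; the Bazett square-root variant is available via the
`exponent` argument. Irregularity is the coefficient of variation of the
beat periods under the population-SD convention, flagged arrhythmic above
0.15 -- a transparent stand-in for proprietary irregularity rules, with the
threshold placed several-fold above the CV of physiological jitter
(~0.02/1.0 s) and well below sustained alternans (CV 0.2 at +/-0.2 s on a
1 s period).

## The synthetic-data module

Scenes are low-pass-filtered seeded white noise (Gaussian blur with sd
`texture_granularity / 2`, rescaled to `[0, 1]`), deformed by a
superposition of radial Gaussian contraction units: at activation `b(t)`,
position `x` displaces by `-A b(t) (x - c) / sigma * exp(-|x - c|^2 /
(2 sigma^2))` toward each center `c`. Frames are rendered by backward
warping (each output pixel samples the texture at `x - d(t, x)`,
bilinearly), so the stored ground truth is exactly the sampling
displacement the matcher should recover; forward splatting would leave
holes and an ill-defined truth. The activation waveform starts at rest
(`b(0) = 0`): a raised cosine for `"sine"`, or a clipped raised-cosine
pulse occupying the final `duty_fraction` of each period for
`"half_wave_pulse"`, so every period opens with a genuine rest interval --
which is also what makes the earliest-minimum reference rule land between
contractions. Additive Gaussian intensity noise is expressed as a fraction
of the `[0, 1]` dynamic range.

Field-potential traces place spikes at cumulative intervals
`beat_period + jitter +/- alternans_delta` (alternating sign), each beat
contributing a biphasic spike (2-ms Gaussian lobes, 55 %/45 % split, 12 ms
apart, peak-to-trough = `spike_amplitude`) and a repolarization bump
(sd = FPD/5, default height 20 % of the spike) peaking `fpd` seconds after
the spike. The last spike is emitted only if a complete beat -- spike, full
repolarization wave and some baseline -- fits before the trace ends, so
every generated beat is analyzable. All generators are pure functions of
their spec, including the seed; no global RNG state is consumed.

What the generator does *not* emulate: phase-contrast optics and cell
morphology, focus drift and stage wander, spatially propagating activation
wavefronts, electrode-specific MEA artifacts, or T-wave morphologies beyond
a single smooth bump. Passing tests therefore demonstrate correctness of
the *algorithms* under the stated physical model, not robustness to every
property of laboratory recordings.

## Study conditions used by the bundled analyses

The packaged tests and the acceptance script run at desk scale chosen to
exercise the method, not to reproduce laboratory statistics:

* videos of 128 x 128 px, 30 frames/s, 20 s (600 frames), one Gaussian
  contraction center (`A = 4` px, `sigma = 36` px), texture granularity
  4 px, beat frequencies 0.2--1.5 Hz, noise 0 or 5 % of the dynamic range;
* oracle-equivalence pairs of 256 x 256 px with uniform integer shifts up
  to the 16-px coarse radius;
* field potentials at 5 kHz for 30 s, beat periods 0.66--1.22 s, FPD
  0.25--0.45 s, 2 % voltage noise, jitter 0.02 s, alternans 0.2--0.25 s.

The 1 px ≈ 1 µm magnification, frame rate and durations are configuration
choices, not claims about any particular instrument.

## Numerical choices and degenerate inputs

* TPS kernel `U(r) = r^2 log r` with an affine null space: `lambda = 0`
  interpolates exactly; affine fields are reproduced exactly for *any*
  `lambda`; collinear or fewer than three valid sites raise an error.
  GCV selects `lambda` jointly across both displacement components on a
  log-spaced grid.
* Matching ties are resolved (smallest magnitude, then lexicographic), so
  identical inputs give bit-identical outputs; a tile with no in-bounds
  candidate is flagged invalid and excluded from spline fits and averages
  rather than raising.
* Central differences are exact for linear fields even at the one-sided
  borders; the interior stencil error is bounded by `h^2/6 max|f'''|`,
  which the tests verify against the closed-form Gaussian-center field.
* Spectra require at least 8 uniform samples; the Parseval identity
  `sum(power) = N * sum((D - mean D)^2)` is preserved to machine precision
  and asserted to 1e-9 relative.
* Pipelines are single-threaded and deterministic; run records carry the
  full configuration, package version and output checksums, and repeated
  runs are verified byte-identical by hash.

## Known limitations

Integer matching bounds per-tile accuracy at rest to about half a pixel
before smoothing; scenes whose peak displacement is well below one pixel
will drown in quantization. The convergence threshold presumes some frames
near rest exist in the recording. FPD detection assumes a monophasic
repolarization wave; biphasic T-wave-like shapes would need a different
extremum rule. The irregularity CV is a summary statistic: it flags
sustained alternans and erratic rhythms but cannot distinguish them, and
short traces (fewer than ~10 beats) make it noisy.
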