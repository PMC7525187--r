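#' Specification of a synthetic field-potential trace
#'
#' Emulates an extracellular MEA recording of a spontaneously beating
#' culture: each beat contributes a sharp biphasic depolarization spike
#' (peak-to-trough height `spike_amplitude`) followed by a smooth
#' repolarization bump whose peak sits `fpd` seconds after the spike.
#' Inter-spike intervals are `beat_period + jitter +/- alternans_delta`
#' with the alternans offset alternating in sign beat to beat.
#'
#' @param sampling_rate samples per second, `>= 1000`.
#' @param duration trace length in seconds.
#' @param beat_period mean inter-spike interval, seconds.
#' @param period_jitter_sd sd of Gaussian interval jitter, seconds.
#' @param alternans_delta alternating interval offset, seconds,
#'   `< beat_period / 2`.
#' @param spike_amplitude peak-to-trough spike height, signal units.
#' @param fpd spike-to-repolarization-peak delay, seconds,
#'   `0 < fpd < beat_period`.
#' @param rep_amplitude height of the repolarization bump (signal units);
#'   default a fifth of the spike amplitude. Setting it to 0 produces a
#'   trace whose FPD is undetectable by construction.
#' @param noise_sd sd of additive Gaussian noise, signal units.
#' @param seed integer seed; the trace is a pure function of its spec.
#' @return An object of class `fp_spec`.
#' @export
fp_spec <- function(sampling_rate = 5000,
                    duration = 30,
                    beat_period = 1.0,
                    period_jitter_sd = 0,
                    alternans_delta = 0,
                    spike_amplitude = 100,
                    fpd = 0.35,
                    rep_amplitude = 0.2 * spike_amplitude,
                    noise_sd = 0,
                    seed = 1L) {
  if (sampling_rate < 1000) stopf("sampling_rate must be >= 1000 Hz")
  if (duration <= 0) stopf("duration must be > 0")
  if (!(beat_period > fpd && fpd > 0))
    stopf("need beat_period > fpd > 0")
  if (period_jitter_sd < 0) stopf("period_jitter_sd must be >= 0")
  if (alternans_delta < 0 || alternans_delta >= beat_period / 2)
    stopf("alternans_delta must lie in [0, beat_period / 2)")
  if (spike_amplitude <= 0) stopf("spike_amplitude must be > 0")
  if (rep_amplitude < 0) stopf("rep_amplitude must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is_count(seed)) stopf("seed must be a positive integer")
  structure(list(sampling_rate = as.numeric(sampling_rate),
                 duration = as.numeric(duration),
                 beat_period = as.numeric(beat_period),
                 period_jitter_sd = as.numeric(period_jitter_sd),
                 alternans_delta = as.numeric(alternans_delta),
                 spike_amplitude = as.numeric(spike_amplitude),
                 fpd = as.numeric(fpd),
                 rep_amplitude = as.numeric(rep_amplitude),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "fp_spec")
}

#' A sampled field-potential trace
#'
#' @param time uniformly spaced timestamps, seconds.
#' @param voltage signal values, same length as `time`.
#' @param sampling_rate samples per second; inferred from `time` if omitted.
#' @return An object of class `fp_trace`.
#' @export
fp_trace <- function(time, voltage, sampling_rate = NULL) {
  if (length(time) != length(voltage)) stopf("time and voltage lengths differ")
  if (length(time) < 2L) stopf("a trace needs at least 2 samples")
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) stopf("sampling must be uniform")
  if (is.null(sampling_rate)) sampling_rate <- 1 / dt[1]
  structure(list(time = as.numeric(time), voltage = as.numeric(voltage),
                 sampling_rate = as.numeric(sampling_rate)),
            class = "fp_trace")
}

#' @export
print.fp_trace <- function(x, ...) {
  cat(sprintf("fp_trace: %.3g s at %g Hz (%d samples)\n",
              length(x$time) / x$sampling_rate, x$sampling_rate,
              length(x$time)))
  invisible(x)
}

# Biphasic spike shape parameters (fractions of spike_amplitude and fixed
# widths): a dominant positive lobe at the spike time and a smaller trough
# 12 ms later; lobes are 2-ms-sd Gaussians, far enough apart that the
# peak-to-trough height equals spike_amplitude to high accuracy.
.spike_pos_frac <- 0.55
.spike_neg_frac <- 0.45
.spike_sd <- 0.002
.spike_trough_delay <- 0.012

#' Generate a synthetic field-potential trace with ground truth
#'
#' Deterministic given `spec$seed`. Ground truth (spike times, realized
#' intervals, the FPD, and per-beat amplitudes) is attached as the
#' `"ground_truth"` attribute.
#'
#' @param spec an [fp_spec()].
#' @return An [fp_trace()]; errors if the FPD does not fit inside the
#'   shortest realized inter-spike interval.
#' @export
generate_field_potential <- function(spec) {
  stopifnot(inherits(spec, "fp_spec"))
  n <- floor(spec$duration * spec$sampling_rate)
  t <- (seq_len(n) - 1) / spec$sampling_rate

  # spike times: first spike half a period in, then cumulative intervals;
  # the margin leaves a complete beat (spike + full repolarization wave and
  # some baseline) between the last spike and the end of the trace
  spikes <- with_seed(spec$seed, {
    s <- spec$beat_period / 2
    out <- s
    k <- 0L
    margin <- spec$fpd * (1 + 6 / 5) + 0.05
    repeat {
      jit <- if (spec$period_jitter_sd > 0) rnorm(1, 0, spec$period_jitter_sd) else 0
      iv <- spec$beat_period + jit +
        spec$alternans_delta * (if (k %% 2L == 0L) 1 else -1)
      if (iv <= 0) iv <- 0.05  # guard against pathological jitter draws
      s <- s + iv
      k <- k + 1L
      if (s > spec$duration - margin) break
      out <- c(out, s)
    }
    out
  })
  if (length(spikes) >= 2 && spec$fpd >= min(diff(spikes)))
    stopf("fpd (%.3g s) must be below the shortest inter-spike interval (%.3g s)",
          spec$fpd, min(diff(spikes)))

  v <- numeric(n)
  sr <- spec$fpd / 5  # repolarization bump width
  for (s in spikes) {
    win <- which(t > s - 0.05 & t < s + spec$fpd + 6 * sr)
    tv <- t[win]
    v[win] <- v[win] +
      .spike_pos_frac * spec$spike_amplitude *
        exp(-(tv - s)^2 / (2 * .spike_sd^2)) -
      .spike_neg_frac * spec$spike_amplitude *
        exp(-(tv - s - .spike_trough_delay)^2 / (2 * .spike_sd^2)) +
      spec$rep_amplitude * exp(-(tv - s - spec$fpd)^2 / (2 * sr^2))
  }
  if (spec$noise_sd > 0)
    v <- v + with_seed(spec$seed + 1L, rnorm(n, 0, spec$noise_sd))

  tr <- fp_trace(t, v, spec$sampling_rate)
  attr(tr, "ground_truth") <- list(spec = spec, spike_times = spikes,
                                   intervals = diff(spikes), fpd = spec$fpd)
  tr
}
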