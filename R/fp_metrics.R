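#' Detect depolarization spikes in a field-potential trace
#'
#' Works on the absolute deviation of the voltage from a running median
#' (so either spike polarity is handled and slow drift is removed). Local
#' maxima of the deviation are kept when they exceed both
#' `prominence_frac` times the global maximum deviation (scale-invariant;
#' the 0.5 default keeps the slower, lower repolarization wave from being
#' called a spike)
#' and `noise_mult` times the MAD of the deviation (an absolute noise floor
#' so a spike-free noisy trace yields no detections). Peaks are then
#' accepted greedily in decreasing height under a refractory spacing.
#'
#' @param trace an [fp_trace()].
#' @param prominence_frac fraction of the global maximum deviation a peak
#'   must reach (default 0.5).
#' @param refractory minimum spacing between spikes, seconds (default 0.2).
#' @param noise_mult noise-floor multiplier on `mad(deviation)` (default 10).
#' @param baseline_window running-median window, seconds (default 0.5).
#' @return Numeric vector of spike times (seconds), possibly empty (with a
#'   warning when nothing is found).
#' @export
detect_spikes <- function(trace, prominence_frac = 0.5, refractory = 0.2,
                          noise_mult = 10, baseline_window = 0.5) {
  stopifnot(inherits(trace, "fp_trace"))
  v <- trace$voltage
  n <- length(v)
  k <- min(odd_window(baseline_window * trace$sampling_rate), odd_window(n - 2))
  dev <- abs(v - runmed(v, k))
  thr <- max(prominence_frac * max(dev), noise_mult * mad(dev))

  core <- 2:(n - 1)
  is_peak <- dev[core] > dev[core - 1] & dev[core] >= dev[core + 1] &
    dev[core] >= thr
  cand <- core[is_peak]
  if (length(cand) == 0) {
    warning("no spikes detected", call. = FALSE)
    return(numeric(0))
  }
  cand <- cand[order(-dev[cand], cand)]
  gap <- refractory * trace$sampling_rate
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(i - kept) >= gap)) kept <- c(kept, i)
  }
  sort(trace$time[kept])
}

odd_window <- function(k) {
  k <- max(3L, as.integer(round(k)))
  if (k %% 2L == 0L) k + 1L else k
}

#' Inter-spike beat periods
#'
#' @param spike_times spike times in seconds (at least 2).
#' @return list with `periods` (successive differences, seconds), `mean`,
#'   `sd` (sample SD), and `status` (`"ok"` or `"undefined"` when fewer
#'   than 2 spikes are available).
#' @export
beat_periods <- function(spike_times) {
  if (length(spike_times) < 2)
    return(list(periods = numeric(0), mean = NA_real_, sd = NA_real_,
                status = "undefined"))
  p <- diff(sort(spike_times))
  list(periods = p, mean = mean(p),
       sd = if (length(p) > 1) sd(p) else NA_real_, status = "ok")
}

#' Per-beat spike amplitude (peak-to-trough)
#'
#' Maximum minus minimum voltage within `+/- window / 2` of each spike
#' time. The window must not reach into the neighboring beat.
#'
#' @param trace an [fp_trace()].
#' @param spike_times spike times, seconds.
#' @param window window width in seconds (default 0.05).
#' @return list with `amplitudes` (per beat) and `mean`.
#' @export
spike_amplitude <- function(trace, spike_times, window = 0.05) {
  stopifnot(inherits(trace, "fp_trace"))
  if (length(spike_times) >= 2 && window >= min(diff(sort(spike_times))))
    stopf("window (%g s) overlaps the adjacent beat", window)
  amps <- vapply(spike_times, function(s) {
    i <- which(trace$time >= s - window / 2 & trace$time <= s + window / 2)
    if (length(i) == 0) return(NA_real_)
    max(trace$voltage[i]) - min(trace$voltage[i])
  }, numeric(1))
  list(amplitudes = amps, mean = mean(amps, na.rm = TRUE))
}

# Gaussian smoothing of a vector (sd in samples), FFT-free, edge-padded.
gauss_smooth <- function(x, sd_samples) {
  half <- max(1L, as.integer(ceiling(3 * sd_samples)))
  k <- exp(-((-half):half)^2 / (2 * sd_samples^2))
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(x))]
}

#' Field potential duration (FPD) per beat
#'
#' FPD is the delay from the depolarization spike to the extremum of the
#' smoothed repolarization wave, searched within
#' `(search_min, search_frac * beat period)` after each spike. A beat whose
#' repolarization extremum stays below `detect_frac` of its spike amplitude
#' is flagged undetected (`NA`).
#'
#' @param trace an [fp_trace()].
#' @param spike_times spike times, seconds.
#' @param search_min start of the search window after the spike, seconds
#'   (default 0.1, past the biphasic spike itself).
#' @param search_frac end of the window as a fraction of the local beat
#'   period (default 0.8).
#' @param smooth_sd sd of the Gaussian smoother, seconds (default 8 ms).
#' @param detect_frac repolarization detectability floor as a fraction of
#'   the per-beat spike amplitude (default 0.05).
#' @return list with `fpd` (per beat, `NA` where undetected), `mean`
#'   (over detected beats), and `detected` (logical).
#' @export
detect_fpd <- function(trace, spike_times, search_min = 0.1,
                       search_frac = 0.8, smooth_sd = 0.008,
                       detect_frac = 0.05) {
  stopifnot(inherits(trace, "fp_trace"))
  ns <- length(spike_times)
  if (ns < 1) return(list(fpd = numeric(0), mean = NA_real_,
                          detected = logical(0)))
  k <- min(odd_window(0.5 * trace$sampling_rate),
           odd_window(length(trace$voltage) - 2))
  resid <- trace$voltage - runmed(trace$voltage, k)
  sm <- gauss_smooth(resid, smooth_sd * trace$sampling_rate)
  amps <- spike_amplitude(trace, spike_times)$amplitudes

  periods <- diff(sort(spike_times))
  med_p <- if (length(periods)) median(periods) else
    (max(trace$time) - spike_times[ns])
  fpd <- rep(NA_real_, ns)
  for (b in seq_len(ns)) {
    p <- if (b < ns) spike_times[b + 1] - spike_times[b] else med_p
    lo <- spike_times[b] + search_min
    hi <- spike_times[b] + search_frac * p
    i <- which(trace$time > lo & trace$time < hi)
    if (length(i) == 0) next
    j <- i[which.max(abs(sm[i]))]
    if (abs(sm[j]) >= detect_frac * amps[b])
      fpd[b] <- trace$time[j] - spike_times[b]
  }
  det <- !is.na(fpd)
  list(fpd = fpd, mean = if (any(det)) mean(fpd[det]) else NA_real_,
       detected = det)
}

#' Fridericia rate correction of the field potential duration
#'
#' `FPDc = FPD / (beat period)^(1/3)` with the beat period in seconds: the
#' standard cube-root rate correction applied to QT-like intervals, so FPDc
#' equals FPD exactly at a 1-second beat period. (Pass `exponent = 1/2` for
#' the Bazett variant.)
#'
#' @param fpd field potential duration(s), seconds, `> 0`.
#' @param beat_period beat period(s), seconds, `> 0`.
#' @param exponent rate-correction exponent (default `1/3`).
#' @return Corrected FPD in seconds (vectorized).
#' @export
fridericia_fpdc <- function(fpd, beat_period, exponent = 1 / 3) {
  if (any(!is.finite(fpd)) || any(fpd <= 0))
    stopf("fpd must be positive")
  if (any(!is.finite(beat_period)) || any(beat_period <= 0))
    stopf("beat_period must be positive")
  fpd / beat_period^exponent
}

#' Beat-period irregularity and arrhythmia flag
#'
#' Coefficient of variation of the beat periods under the population-SD
#' convention (divide by `n`); the trace is flagged arrhythmic when the CV
#' exceeds `cv_threshold`. A transparent stand-in for proprietary
#' beat-irregularity rules.
#'
#' @param periods inter-spike intervals, seconds (at least 3).
#' @param cv_threshold flag threshold on the CV (default 0.15).
#' @return list with `cv`, `arrhythmic`, `status`.
#' @export
irregularity <- function(periods, cv_threshold = 0.15) {
  if (length(periods) < 3)
    return(list(cv = NA_real_, arrhythmic = NA, status = "undefined"))
  m <- mean(periods)
  if (m == 0) return(list(cv = NA_real_, arrhythmic = NA,
                          status = "undefined"))
  cv <- sqrt(mean((periods - m)^2)) / m
  list(cv = cv, arrhythmic = cv > cv_threshold, status = "ok")
}

#' All field-potential metrics of one trace
#'
#' Runs spike detection and derives beat periods, per-beat and mean spike
#' amplitude, FPD, Fridericia-corrected FPD (from the mean FPD and mean
#' beat period), and the irregularity flag.
#'
#' @param trace an [fp_trace()].
#' @param prominence_frac,refractory,noise_mult spike detection parameters
#'   (see [detect_spikes()]).
#' @param amp_window amplitude window, seconds.
#' @param cv_threshold irregularity flag threshold.
#' @param ... further arguments passed to [detect_fpd()].
#' @return An object of class `beat_metrics`.
#' @export
compute_beat_metrics <- function(trace, prominence_frac = 0.5,
                                 refractory = 0.2, noise_mult = 10,
                                 amp_window = 0.05, cv_threshold = 0.15,
                                 ...) {
  stopifnot(inherits(trace, "fp_trace"))
  if (length(trace$time) / trace$sampling_rate < 2)
    stopf("metric computation needs at least 2 s of trace")
  spikes <- suppressWarnings(
    detect_spikes(trace, prominence_frac, refractory, noise_mult))
  bp <- beat_periods(spikes)
  amp <- if (length(spikes)) spike_amplitude(trace, spikes, amp_window) else
    list(amplitudes = numeric(0), mean = NA_real_)
  fpd <- detect_fpd(trace, spikes, ...)
  irr <- irregularity(bp$periods, cv_threshold)
  fpdc <- if (!is.na(fpd$mean) && !is.na(bp$mean))
    fridericia_fpdc(fpd$mean, bp$mean) else NA_real_
  structure(list(spike_times = spikes,
                 beat_periods = bp$periods,
                 mean_beat_period = bp$mean,
                 sd_beat_period = bp$sd,
                 fpd = fpd$fpd, mean_fpd = fpd$mean,
                 fpd_detected = fpd$detected,
                 fpdc = fpdc,
                 spike_amplitudes = amp$amplitudes,
                 mean_spike_amplitude = amp$mean,
                 irregularity_cv = irr$cv,
                 arrhythmic = irr$arrhythmic,
                 n_beats = length(spikes)),
            class = "beat_metrics")
}

#' @export
print.beat_metrics <- function(x, ...) {
  cat(sprintf(paste0("beat_metrics: %d beats, period %.3f s, FPD %.3f s, ",
                     "FPDc %.3f s, amplitude %.3g, CV %.3f%s\n"),
              x$n_beats, x$mean_beat_period, x$mean_fpd, x$fpdc,
              x$mean_spike_amplitude, x$irregularity_cv,
              if (isTRUE(x$arrhythmic)) " [arrhythmic]" else ""))
  invisible(x)
}

#' Baseline-vs-treated contrast of field-potential metrics
#'
#' Fold changes (treated / baseline) of beat period, FPDc and spike
#' amplitude with direction labels: chronotropy "up" when the beat period
#' shortens, FPDc "prolonged"/"shortened", and the arrhythmia-flag
#' transition. Metrics undefined on either side give `NA` folds flagged in
#' `missing`.
#'
#' @param baseline,treated `beat_metrics` objects.
#' @param tol relative dead-band around 1 for the direction labels
#'   (default 0.02).
#' @return An object of class `drug_contrast` (a list).
#' @export
drug_contrast <- function(baseline, treated, tol = 0.02) {
  stopifnot(inherits(baseline, "beat_metrics"),
            inherits(treated, "beat_metrics"))
  fold <- function(a, b) if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
  pf <- fold(treated$mean_beat_period, baseline$mean_beat_period)
  ff <- fold(treated$fpdc, baseline$fpdc)
  af <- fold(treated$mean_spike_amplitude, baseline$mean_spike_amplitude)
  lab <- function(f, down, up) {
    if (is.na(f)) NA_character_
    else if (f < 1 - tol) down
    else if (f > 1 + tol) up
    else "unchanged"
  }
  structure(list(
    beat_period_fold = pf,
    fpdc_fold = ff,
    amplitude_fold = af,
    chronotropy = lab(pf, "up", "down"),
    fpdc_direction = lab(ff, "shortened", "prolonged"),
    amplitude_direction = lab(af, "decreased", "increased"),
    arrhythmia_transition = paste(
      ifelse(isTRUE(baseline$arrhythmic), "arrhythmic", "regular"), "->",
      ifelse(isTRUE(treated$arrhythmic), "arrhythmic", "regular")),
    missing = c(beat_period = is.na(pf), fpdc = is.na(ff),
                amplitude = is.na(af))),
    class = "drug_contrast")
}

#' @export
print.drug_contrast <- function(x, ...) {
  cat(sprintf(paste0("drug_contrast: period x%.3f (chronotropy %s), ",
                     "FPDc x%.3f (%s), amplitude x%.3f (%s), %s\n"),
              x$beat_period_fold, x$chronotropy, x$fpdc_fold,
              x$fpdc_direction, x$amplitude_fold, x$amplitude_direction,
              x$arrhythmia_transition))
  invisible(x)
}
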