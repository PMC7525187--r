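#' Per-frame motion magnitude from consecutive-frame flow
#'
#' A cheap single-stage pass: the coarse matcher is run between each pair of
#' consecutive frames and `V(t)` is the spatial mean displacement magnitude
#' over valid tiles. The last value is duplicated from its predecessor so
#' the trace indexes frames. The mean match dissimilarity per pair is kept
#' alongside: integer matching quantizes `V` to zero both in genuine rest
#' intervals and across the instant of peak contraction, and the residual
#' score separates the two when a reference frame is selected.
#'
#' @param sequence an [image_sequence()].
#' @param tile_size,step,search_radius coarse-matcher parameters; defaults
#'   (32-px abutting tiles, 8-px radius) keep this pass cheap.
#' @return An object of class `motion_trace`: list with `V`, `scores`
#'   (per-frame mean dissimilarity) and `n`.
#' @export
frame_motion <- function(sequence, tile_size = 32, step = tile_size,
                         search_radius = 8) {
  stopifnot(inherits(sequence, "image_sequence"))
  nf <- length(sequence$frames)
  grid <- tile_grid(dim(sequence$frames[[1]]), tile_size, step)
  V <- numeric(nf)
  sc <- numeric(nf)
  for (t in seq_len(nf - 1)) {
    f <- coarse_field(sequence$frames[[t]], sequence$frames[[t + 1]],
                      grid = grid, search_radius = search_radius)
    ok <- f$valid
    V[t] <- mean(sqrt(f$vectors[ok, 1]^2 + f$vectors[ok, 2]^2))
    sc[t] <- mean(f$scores[ok])
  }
  V[nf] <- V[nf - 1]
  sc[nf] <- sc[nf - 1]
  structure(list(V = V, scores = sc, n = nf), class = "motion_trace")
}

#' Select the resting reference frame t*
#'
#' Returns the frame minimizing the motion trace `V(t)`, i.e. a frame
#' between two contraction cycles where movement is minimal. Among frames
#' tied at the minimum, the one with the lowest mean match dissimilarity is
#' preferred (earliest frame on remaining ties, and earliest overall when no
#' scores are available), which keeps the choice deterministic and anchored
#' in a true rest interval.
#'
#' @param motion a `motion_trace` from [frame_motion()], or a bare numeric
#'   vector of motion values.
#' @return Integer frame index `t*` (1-based).
#' @export
select_reference <- function(motion) {
  V <- if (inherits(motion, "motion_trace")) motion$V else as.numeric(motion)
  scores <- if (inherits(motion, "motion_trace")) motion$scores else NULL
  cand <- which(V == min(V))
  if (length(cand) > 1 && !is.null(scores)) {
    s <- scores[cand]
    cand <- cand[s == min(s)]
  }
  cand[1]
}

#' Beat pattern D(t) from displacement fields
#'
#' `D(t)` is the spatial mean of the displacement magnitude `|d(t, x)|`
#' over valid grid centers; frames with no valid tile get `NA`. By
#' construction `D(t*) = 0` exactly (the reference frame matched against
#' itself).
#'
#' @param fields a `flow_result` or a list of `displacement_field`s sharing
#'   one grid.
#' @param frame_interval seconds between frames (taken from the
#'   `flow_result` if given).
#' @return An object of class `beat_trace`: list with `D` (pixels), `times`
#'   (seconds), `frame_interval` and `reference`.
#' @export
beat_pattern <- function(fields, frame_interval = NULL) {
  if (inherits(fields, "flow_result")) {
    if (is.null(frame_interval)) frame_interval <- fields$frame_interval
    reference <- fields$reference_index
    fields <- fields$fields
  } else {
    reference <- fields[[1]]$reference
  }
  if (is.null(frame_interval)) stopf("frame_interval is required")
  D <- vapply(fields, function(f) {
    ok <- f$valid
    if (!any(ok)) return(NA_real_)
    mean(sqrt(f$vectors[ok, 1]^2 + f$vectors[ok, 2]^2))
  }, numeric(1))
  structure(list(D = D, times = (seq_along(D) - 1) * frame_interval,
                 frame_interval = frame_interval, reference = reference),
            class = "beat_trace")
}

#' Construct a beat trace directly
#'
#' @param D non-negative displacement magnitudes per frame (pixels).
#' @param frame_interval seconds between samples.
#' @param reference optional reference frame index.
#' @return A `beat_trace`.
#' @export
beat_trace <- function(D, frame_interval, reference = NA_integer_) {
  if (frame_interval <= 0) stopf("frame_interval must be > 0")
  structure(list(D = as.numeric(D),
                 times = (seq_along(D) - 1) * frame_interval,
                 frame_interval = frame_interval, reference = reference),
            class = "beat_trace")
}

#' Discrete-Fourier power spectrum of a beat pattern
#'
#' The mean-subtracted `D(t)` is transformed with the DFT and the power is
#' the squared magnitude of the coefficients; the one-sided spectrum (bins
#' up to Nyquist) is reported and no taper window is applied. The sum of
#' power over all `N` bins, kept as `total_power`, satisfies Parseval's
#' identity `total_power = N * sum((D - mean(D))^2)`.
#'
#' @param trace a `beat_trace` with at least 8 uniformly sampled values.
#' @return An object of class `power_spectrum`: `frequencies` (Hz), `power`,
#'   `n`, `frame_interval`, `total_power`.
#' @export
power_spectrum <- function(trace) {
  stopifnot(inherits(trace, "beat_trace"))
  D <- trace$D
  if (length(D) < 8) stopf("need at least 8 samples for a spectrum")
  if (anyNA(D)) stopf("beat trace contains missing frames")
  dt <- diff(trace$times)
  if (any(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1)))
    stopf("sampling must be uniform")
  n <- length(D)
  x <- D - mean(D)
  X <- fft(x)
  pw <- Mod(X)^2
  half <- seq_len(floor(n / 2) + 1)
  structure(list(frequencies = (half - 1) / (n * trace$frame_interval),
                 power = pw[half],
                 n = n, frame_interval = trace$frame_interval,
                 total_power = sum(pw)),
            class = "power_spectrum")
}

#' Dominant beat frequency of a power spectrum
#'
#' Bin-center frequency with maximal power at or above `min_freq`; ties go
#' to the lowest frequency. Harmonics of a non-sinusoidal beat appear at
#' integer multiples of the returned fundamental.
#'
#' @param spectrum a `power_spectrum`.
#' @param min_freq lower frequency bound (Hz), default 0.05 to exclude
#'   drift; must exceed the DC bin.
#' @return list with `frequency` (Hz), `power`, and `harmonics` (the integer
#'   multiples of the fundamental up to Nyquist).
#' @export
dominant_frequency <- function(spectrum, min_freq = 0.05) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (min_freq <= 0) stopf("min_freq must be above the DC bin")
  keep <- spectrum$frequencies >= min_freq
  if (!any(keep)) stopf("no spectral bins at or above min_freq = %g", min_freq)
  fr <- spectrum$frequencies[keep]
  pw <- spectrum$power[keep]
  i <- which.max(pw)  # first maximum = lowest-frequency tie
  f <- fr[i]
  nyq <- max(spectrum$frequencies)
  list(frequency = f, power = pw[i], harmonics = f * seq_len(floor(nyq / f)))
}
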