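#' Contraction center for a synthetic beating scene
#'
#' A radially symmetric Gaussian contraction unit. At full activation the
#' tissue at position `x` is displaced toward the center `c` by
#' `A * (|x - c| / sigma) * exp(-|x - c|^2 / (2 sigma^2))` pixels, i.e. the
#' peak displacement `A * exp(-1/2)` occurs on the ring `|x - c| = sigma`.
#'
#' @param position numeric length-2, center (row, col) in pixels (1-based).
#' @param amplitude peak displacement scale `A` in pixels, `>= 0`.
#' @param radius Gaussian spatial extent `sigma` in pixels, `> 0`.
#' @return An object of class `contraction_center`.
#' @export
contraction_center <- function(position, amplitude, radius) {
  if (length(position) != 2L || !all(is.finite(position)))
    stopf("position must be a finite (row, col) pair")
  if (!is.numeric(amplitude) || length(amplitude) != 1L || !is.finite(amplitude))
    stopf("amplitude must be a single finite number")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stopf("radius (sigma) must be > 0")
  structure(list(position = as.numeric(position),
                 amplitude = as.numeric(amplitude),
                 radius = as.numeric(radius)),
            class = "contraction_center")
}

#' Specification of a synthetic beating-monolayer scene
#'
#' Defines a textured image deformed by one or more periodic Gaussian
#' contraction centers, observed at a fixed frame rate with additive
#' Gaussian intensity noise. Texture intensities live in `[0, 1]`, so
#' `noise_sigma` is expressed as a fraction of the dynamic range.
#'
#' The activation waveform `b(t)` is in `[0, 1]` with `b(0) = 0`:
#' * `"sine"`: raised cosine `b(t) = (1 - cos(2 pi f t)) / 2`.
#' * `"half_wave_pulse"`: a clipped raised-cosine pulse of width
#'   `duty_fraction / f` placed at the end of each period, so every
#'   period starts with a rest interval where `b(t) = 0` exactly.
#'
#' @param image_size integer length-2 `(H, W)` in pixels.
#' @param texture_seed integer seed; the scene is a pure function of its spec.
#' @param texture_granularity correlation length of the random texture, pixels.
#' @param centers list of [contraction_center()] objects (a single center is
#'   also accepted); all centers must lie within the image bounds.
#' @param beat_frequency beats per second (Hz), `> 0`.
#' @param waveform `"sine"` or `"half_wave_pulse"`.
#' @param duty_fraction pulse width as a fraction of the period, in `(0, 1]`.
#' @param noise_sigma sd of additive Gaussian intensity noise, `>= 0`.
#' @param frame_rate frames per second (Hz); must exceed `2 * beat_frequency`.
#' @param duration recording length in seconds.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(128L, 128L),
                       texture_seed = 1L,
                       texture_granularity = 4,
                       centers = list(),
                       beat_frequency = 1,
                       waveform = c("half_wave_pulse", "sine"),
                       duty_fraction = 0.3,
                       noise_sigma = 0,
                       frame_rate = 30,
                       duration = 20) {
  waveform <- match.arg(waveform)
  if (length(image_size) != 2L || any(image_size < 8))
    stopf("image_size must be (H, W) with both dimensions >= 8")
  if (!is_count(texture_seed)) stopf("texture_seed must be a positive integer")
  if (!is.numeric(texture_granularity) || texture_granularity < 1)
    stopf("texture_granularity must be >= 1 pixel")
  if (inherits(centers, "contraction_center")) centers <- list(centers)
  if (!all(vapply(centers, inherits, logical(1), "contraction_center")))
    stopf("centers must be contraction_center objects")
  if (beat_frequency <= 0) stopf("beat_frequency must be > 0")
  if (frame_rate <= 2 * beat_frequency)
    stopf("frame_rate must exceed 2 x beat_frequency (Nyquist margin)")
  if (duty_fraction <= 0 || duty_fraction > 1)
    stopf("duty_fraction must lie in (0, 1]")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (duration <= 0) stopf("duration must be > 0")
  for (cc in centers) {
    p <- cc$position
    if (p[1] < 1 || p[1] > image_size[1] || p[2] < 1 || p[2] > image_size[2])
      stopf("contraction center (%.1f, %.1f) lies outside the image", p[1], p[2])
  }
  structure(list(image_size = as.integer(image_size),
                 texture_seed = as.integer(texture_seed),
                 texture_granularity = as.numeric(texture_granularity),
                 centers = centers,
                 beat_frequency = as.numeric(beat_frequency),
                 waveform = waveform,
                 duty_fraction = as.numeric(duty_fraction),
                 noise_sigma = as.numeric(noise_sigma),
                 frame_rate = as.numeric(frame_rate),
                 duration = as.numeric(duration)),
            class = "scene_spec")
}

#' Activation waveform b(t) of a scene
#'
#' @param spec a [scene_spec()].
#' @param t time(s) in seconds (vectorized).
#' @return Values of `b(t)` in `[0, 1]`.
#' @export
waveform_value <- function(spec, t) {
  stopifnot(inherits(spec, "scene_spec"))
  phase <- (t * spec$beat_frequency) %% 1
  if (spec$waveform == "sine") {
    0.5 * (1 - cos(2 * pi * phase))
  } else {
    d <- spec$duty_fraction
    u <- (phase - (1 - d)) / d
    ifelse(u >= 0, 0.5 * (1 - cos(2 * pi * u)), 0)
  }
}

#' Generate the static texture of a scene
#'
#' Low-pass-filtered seeded white noise: Gaussian smoothing (circular, via
#' the FFT) of an i.i.d. normal field with smoothing sd
#' `texture_granularity / 2`, rescaled to exactly span `[0, 1]`. The result
#' is deterministic given `texture_seed` and its spatial autocorrelation
#' length scales with `texture_granularity`.
#'
#' @param spec a [scene_spec()].
#' @return An `H x W` numeric matrix with values in `[0, 1]`.
#' @export
generate_texture <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  noise <- with_seed(spec$texture_seed, matrix(rnorm(H * W), H, W))
  sigma <- spec$texture_granularity / 2
  fr <- (c(0:floor(H / 2), -(ceiling(H / 2) - 1):-1)) / H
  fc <- (c(0:floor(W / 2), -(ceiling(W / 2) - 1):-1)) / W
  att <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, "+"))
  sm <- Re(fft(fft(noise) * att, inverse = TRUE)) / (H * W)
  (sm - min(sm)) / (max(sm) - min(sm))
}

#' Analytic ground-truth displacement field of a scene
#'
#' The displacement at time `t` and position `x` is the superposition over
#' contraction centers of
#' `-A * b(t) * (x - c) / sigma * exp(-|x - c|^2 / (2 sigma^2))`,
#' pointing radially inward toward each center while `b(t) > 0`.
#'
#' @param spec a [scene_spec()].
#' @param t time in seconds, within `[0, duration]`.
#' @param x numeric matrix `n x 2` of (row, col) pixel positions (a single
#'   length-2 vector is also accepted).
#' @return `n x 2` matrix of (drow, dcol) displacements in pixels.
#' @export
displacement_at <- function(spec, t, x) {
  stopifnot(inherits(spec, "scene_spec"))
  if (t < 0 || t > spec$duration)
    stopf("t = %g lies outside [0, duration = %g]", t, spec$duration)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  b <- waveform_value(spec, t)
  d <- matrix(0, nrow(x), 2)
  if (b == 0 || length(spec$centers) == 0) return(d)
  for (cc in spec$centers) {
    dr <- x[, 1] - cc$position[1]
    dc <- x[, 2] - cc$position[2]
    g <- exp(-(dr^2 + dc^2) / (2 * cc$radius^2))
    k <- -cc$amplitude * b * g / cc$radius
    d[, 1] <- d[, 1] + k * dr
    d[, 2] <- d[, 2] + k * dc
  }
  d
}

# Bilinear sampling of image `img` at real-valued (row, col) positions,
# clamped to the image bounds.
bilinear_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(r, 1), H)
  c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  wr <- r - r0; wc <- c - c0
  i00 <- (c0 - 1) * H + r0
  img[i00]       * (1 - wr) * (1 - wc) +
  img[i00 + 1]   * wr       * (1 - wc) +
  img[i00 + H]   * (1 - wr) * wc +
  img[i00 + H + 1] * wr     * wc
}

#' Render one frame of a synthetic scene
#'
#' Backward warping: each output pixel `x` samples the texture at
#' `x - d(t, x)` with bilinear interpolation, then zero-mean Gaussian noise
#' of sd `noise_sigma` is added (pass `noise = FALSE` for the clean warp).
#' With `noise_sigma = 0` and `b(t) = 0` the frame equals the texture.
#'
#' @param spec a [scene_spec()].
#' @param t time in seconds.
#' @param texture texture matrix from [generate_texture()]; regenerated if
#'   omitted.
#' @param noise add the spec's Gaussian noise (uses the current RNG stream).
#' @return An `H x W` numeric frame.
#' @export
render_frame <- function(spec, t, texture = NULL, noise = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(texture)) texture <- generate_texture(spec)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  x <- cbind(rep(seq_len(H), times = W), rep(seq_len(W), each = H))
  d <- displacement_at(spec, t, x)
  if (any(abs(d) >= pmax(H, W)))
    stopf("displacement magnitude exceeds the image size")
  frame <- matrix(bilinear_sample(texture, x[, 1] - d[, 1], x[, 2] - d[, 2]),
                  H, W)
  if (noise && spec$noise_sigma > 0)
    frame <- frame + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
  frame
}

#' An ordered stack of grayscale frames
#'
#' @param frames list of numeric matrices sharing one shape.
#' @param frame_interval seconds between consecutive frames, `> 0`.
#' @return An object of class `image_sequence` with elements `frames`,
#'   `frame_interval` and `times`.
#' @export
image_sequence <- function(frames, frame_interval) {
  if (length(frames) < 3L) stopf("an image sequence needs at least 3 frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1])) stopf("all frames must share one shape")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stopf("frame_interval must be > 0")
  structure(list(frames = frames,
                 frame_interval = as.numeric(frame_interval),
                 times = (seq_along(frames) - 1) * frame_interval),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_sequence: %d frames of %d x %d px, interval %.4g s\n",
              length(x$frames), d[1], d[2], x$frame_interval))
  invisible(x)
}

#' Generate a beating-monolayer video with analytic ground truth
#'
#' Renders `floor(duration * frame_rate)` frames at uniform timestamps
#' starting at `t = 0`. Ground truth (waveform values, the analytic
#' displacement field sampled on a regular lattice, and the resulting true
#' beat pattern) is attached as the `"ground_truth"` attribute for test use.
#'
#' @param spec a [scene_spec()].
#' @param gt_step lattice spacing (pixels) for the stored ground-truth field.
#' @return An [image_sequence()] with attribute `ground_truth`: a list with
#'   `spec`, `times`, `b` (waveform per frame), `grid` (lattice positions),
#'   `d` (frames x points x 2 array) and `D_true` (mean `|d|` per frame).
#' @export
generate_video <- function(spec, gt_step = 8) {
  stopifnot(inherits(spec, "scene_spec"))
  nf <- floor(spec$duration * spec$frame_rate)
  if (nf < 3) stopf("spec yields fewer than 3 frames")
  H <- spec$image_size[1]; W <- spec$image_size[2]
  dt <- 1 / spec$frame_rate
  times <- (seq_len(nf) - 1) * dt
  texture <- generate_texture(spec)

  gr <- seq(1, H, by = gt_step)
  gc <- seq(1, W, by = gt_step)
  grid <- cbind(rep(gr, times = length(gc)), rep(gc, each = length(gr)))
  d <- array(0, c(nf, nrow(grid), 2))
  b <- waveform_value(spec, times)

  frames <- vector("list", nf)
  with_seed(spec$texture_seed + 1L, {
    for (i in seq_len(nf)) {
      frames[[i]] <- render_frame(spec, times[i], texture, noise = TRUE)
      d[i, , ] <- displacement_at(spec, times[i], grid)
    }
  })
  seq_out <- image_sequence(frames, dt)
  attr(seq_out, "ground_truth") <- list(
    spec = spec, times = times, b = b, grid = grid, d = d,
    D_true = apply(d, 1, function(m) mean(sqrt(m[, 1]^2 + m[, 2]^2))))
  seq_out
}
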