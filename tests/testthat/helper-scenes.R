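# Shared fixture builders. Everything is generated in code; scenes are kept
# small so the default test run stays fast.

# A small single-center beating scene.
small_scene <- function(seed = 1, image_size = c(96, 96), amplitude = 3,
                        sigma = 28, f = 1, noise = 0, duration = 6,
                        frame_rate = 30, waveform = "half_wave_pulse",
                        duty = 0.3) {
  scene_spec(image_size = image_size, texture_seed = seed,
             texture_granularity = 4,
             centers = contraction_center((image_size + 1) / 2, amplitude,
                                          sigma),
             beat_frequency = f, waveform = waveform, duty_fraction = duty,
             noise_sigma = noise, frame_rate = frame_rate,
             duration = duration)
}

# Flow parameters sized for the small scenes above.
small_flow <- function(video, ...) {
  compute_flow(video, tile_size = 48, fine_tile = 24, search_radius = 6,
               fine_radius = 4, ...)
}

# A pair of frames related by a circular integer shift (exact match
# everywhere the shifted window stays in bounds).
shifted_pair <- function(seed, n = 96, shift = c(3, -2)) {
  tx <- with_test_seed(seed, matrix(rnorm(n * n), n, n))
  idx <- function(k, s) ((seq_len(k) - 1 - s) %% k) + 1
  list(reference = tx, moving = tx[idx(n, shift[1]), idx(n, shift[2])],
       shift = shift)
}

runif_det <- function(n, lo, hi) with_test_seed(999, runif(n, lo, hi))

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Brute-force single-tile matcher used as the independent oracle for
# match_tile: plain R loops over every candidate shift.
brute_match <- function(reference, moving, origin, tile, radius) {
  H <- nrow(moving); W <- ncol(moving)
  ref_tile <- reference[origin[1]:(origin[1] + tile - 1),
                        origin[2]:(origin[2] + tile - 1)]
  rows <- list()
  for (dr in -radius:radius) for (dc in -radius:radius) {
    rr <- origin[1] + dr; cc <- origin[2] + dc
    if (rr < 1 || cc < 1 || rr + tile - 1 > H || cc + tile - 1 > W) next
    cand <- moving[rr:(rr + tile - 1), cc:(cc + tile - 1)]
    rows[[length(rows) + 1]] <- c(dr, dc, sum((cand - ref_tile)^2))
  }
  if (length(rows) == 0)
    return(list(shift = c(0L, 0L), score = NA_real_, valid = FALSE))
  m <- do.call(rbind, rows)
  ord <- order(m[, 3], m[, 1]^2 + m[, 2]^2, m[, 1], m[, 2])
  list(shift = as.integer(m[ord[1], 1:2]), score = sqrt(m[ord[1], 3]),
       valid = TRUE)
}

# Analytic convergence (-divergence) of a single Gaussian contraction
# center: (A b g / sigma) (2 - r^2 / sigma^2), g = exp(-r^2 / (2 sigma^2)).
analytic_convergence <- function(x, center, A, sigma, b = 1) {
  r2 <- (x[, 1] - center[1])^2 + (x[, 2] - center[2])^2
  (A * b / sigma) * exp(-r2 / (2 * sigma^2)) * (2 - r2 / sigma^2)
}

# Build a displacement_field directly from a vector-valued function on a
# regular lattice (used to feed closed-form fields to the divergence map).
field_from_function <- function(fun, rows, cols, tile = 1) {
  origins <- cbind(rep(rows, times = length(cols)),
                   rep(cols, each = length(rows)))
  grid <- structure(list(origins = origins,
                         centers = origins + (tile - 1) / 2,
                         rows = rows, cols = cols,
                         tile = as.integer(tile), step = diff(rows[1:2]),
                         shape = c(max(rows) + tile, max(cols) + tile)),
                    class = "tile_grid")
  vec <- fun(grid$centers)
  structure(list(grid = grid, vectors = vec,
                 scores = rep(0, nrow(vec)),
                 valid = rep(TRUE, nrow(vec)),
                 level = "fine", t = 1L, reference = 1L),
            class = "displacement_field")
}
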