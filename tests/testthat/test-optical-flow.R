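# Matching is validated against a plain-R exhaustive oracle, then the
# two-stage pipeline against constructed shifts and the analytic scene field.

test_that("match_tile equals the brute-force oracle on random toy images", {
  for (seed in 1:6) {
    img <- with_test_seed(seed, matrix(rnorm(81), 9, 9))
    mov <- with_test_seed(seed + 100, matrix(rnorm(81), 9, 9))
    for (origin in list(c(4, 4), c(2, 6), c(6, 2))) {
      got <- match_tile(img, mov, origin, tile = 3, search_radius = 2)
      want <- brute_match(img, mov, origin, tile = 3, radius = 2)
      expect_identical(got$shift, want$shift)
      expect_equal(got$score, want$score, tolerance = 1e-10)
    }
  }
})

test_that("match_tile identity, constructed shift, and tie-breaking", {
  pr <- shifted_pair(3, n = 64, shift = c(3, -2))
  same <- match_tile(pr$reference, pr$reference, c(20, 20), 16, 5)
  expect_identical(same$shift, c(0L, 0L))
  expect_equal(same$score, 0)

  hit <- match_tile(pr$reference, pr$moving, c(25, 25), 16, 4)
  expect_identical(hit$shift, c(3L, -2L))
  expect_equal(hit$score, 0, tolerance = 1e-12)

  # constant images: every shift scores 0; smallest magnitude wins
  flat <- matrix(1, 32, 32)
  tie <- match_tile(flat, flat, c(10, 10), 8, 3)
  expect_identical(tie$shift, c(0L, 0L))

  # no in-bounds candidate -> flagged invalid, not an error
  inv <- match_tile(flat, flat, c(1, 1), 8, 0, predicted = c(-30, 0))
  expect_false(inv$valid)
})

test_that("coarse_field recovers uniform translation and correlates with the
           analytic contraction field", {
  pr <- shifted_pair(7, n = 128, shift = c(5, 0))
  cf <- coarse_field(pr$reference, pr$moving, tile_size = 64, step = 32,
                     search_radius = 6)
  # interior tiles (shifted window in bounds) are exact
  interior <- cf$grid$origins[, 1] + 5 + 64 - 1 <= 128 & cf$grid$origins[, 1] + 5 >= 1
  expect_true(all(cf$vectors[interior, 1] == 5))
  expect_true(all(cf$vectors[interior, 2] == 0))

  expect_error(coarse_field(matrix(0, 32, 32), matrix(0, 32, 32),
                            tile_size = 64), "smaller")

  sp <- small_scene(seed = 21, image_size = c(128, 128), amplitude = 4,
                    sigma = 40, f = 1, duration = 2)
  tx <- generate_texture(sp)
  tpeak <- (1 - sp$duty_fraction / 2) / sp$beat_frequency
  mv <- render_frame(sp, tpeak, tx)
  cf2 <- coarse_field(tx, mv, tile_size = 64, step = 32, search_radius = 6)
  truth <- displacement_at(sp, tpeak, cf2$grid$centers)
  ok <- cf2$valid
  cosim <- sum(cf2$vectors[ok, ] * truth[ok, ]) /
    (sqrt(sum(cf2$vectors[ok, ]^2)) * sqrt(sum(truth[ok, ]^2)))
  expect_gt(cosim, 0.9)
})

test_that("thin-plate spline: interpolation at lambda 0, affine reproduction
           at any lambda, and denoising of a smooth field", {
  x <- as.matrix(expand.grid(seq(5, 95, by = 15), seq(5, 95, by = 15)))
  y <- cbind(sin(x[, 1] / 20), cos(x[, 2] / 25))

  fit0 <- tps_fit(x, y, lambda = 0)
  expect_equal(fit0$fitted, y, tolerance = 1e-8)

  # affine field reproduced exactly everywhere, even with heavy smoothing
  M <- matrix(c(0.02, -0.01, 0.03, 0.015), 2)
  b <- c(1, -2)
  ya <- t(M %*% t(x) + b)
  new <- cbind(runif_det(12, 1, 99), runif_det(12, 1, 99))
  for (lam in c(0, 1, 100)) {
    fita <- tps_fit(x, ya, lambda = lam)
    expect_equal(predict(fita, new), t(M %*% t(new) + b), tolerance = 1e-6)
  }

  # noisy samples of a smooth sinusoid: the smoothed fit beats the samples
  truth <- cbind(2 * sin(2 * pi * x[, 1] / 100), 2 * cos(2 * pi * x[, 2] / 100))
  noisy <- truth + with_test_seed(42, matrix(rnorm(length(truth), 0, 0.5),
                                             ncol = 2))
  fitn <- tps_fit(x, noisy, lambda = "gcv")
  rms <- function(m) sqrt(mean(m^2))
  expect_lt(rms(fitn$fitted - truth), rms(noisy - truth))

  # collinear sites are degenerate
  xc <- cbind(1:5, 2 * (1:5))
  expect_error(tps_fit(xc, cbind(1:5, 1:5), 0), "collinear")
})

test_that("tps_smooth excludes invalid tiles and evaluates anywhere", {
  pr <- shifted_pair(9, n = 96, shift = c(2, 1))
  # margin keeps every shifted window in bounds -> all matches exact
  grid <- tile_grid(c(96, 96), 32, 16, margin = 4)
  cf <- coarse_field(pr$reference, pr$moving, grid = grid, search_radius = 4)
  expect_true(all(cf$vectors[, 1] == 2 & cf$vectors[, 2] == 1))
  cf$valid[5] <- FALSE
  cf$vectors[5, ] <- c(50, 50)  # garbage that must be ignored
  sm <- tps_smooth(cf, lambda = 0)
  ev <- attr(sm, "evaluator")
  keep <- seq_along(cf$valid) != 5
  expect_equal(sm$vectors[keep, ], cf$vectors[keep, ], tolerance = 1e-6)
  # the constant field is affine, so even the dropped site is restored
  expect_equal(sm$vectors[5, ], c(2, 1), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(ev(matrix(c(40.5, 40.5), 1)), matrix(c(2, 1), 1),
               tolerance = 1e-6)
})

test_that("fine_field composes prediction and residual; two-stage equals a
           single-stage exhaustive search on uniform shifts", {
  # shift beyond the fine radius is recovered via the coarse prediction
  pr <- shifted_pair(13, n = 128, shift = c(7, 0))
  cf <- coarse_field(pr$reference, pr$moving,
                     grid = tile_grid(c(128, 128), 64, 32, margin = 10),
                     search_radius = 10)
  sm <- tps_smooth(cf, lambda = 0)
  grid <- tile_grid(c(128, 128), 32, 16, margin = 10)
  ff <- fine_field(pr$reference, pr$moving, sm, grid = grid, fine_radius = 4)
  expect_true(all(ff$vectors[, 1] == 7 & ff$vectors[, 2] == 0))
  # locality: residual within the fine radius
  expect_true(all(abs(ff$vectors - attr(ff, "prediction")) <= 4))

  # oracle equivalence on small uniform shifts, several seeds
  for (seed in 1:5) {
    pr <- shifted_pair(seed + 50, n = 128, shift = c(2, 1))
    cgrid <- tile_grid(c(128, 128), 64, 32, margin = 8)
    fgrid <- tile_grid(c(128, 128), 32, 16, margin = 8)
    cf <- coarse_field(pr$reference, pr$moving, grid = cgrid,
                       search_radius = 8)
    ff <- fine_field(pr$reference, pr$moving, tps_smooth(cf, lambda = 0),
                     grid = fgrid, fine_radius = 4)
    oracle <- coarse_field(pr$reference, pr$moving, grid = fgrid,
                           search_radius = 8)
    expect_identical(ff$vectors, oracle$vectors)
  }
})

test_that("compute_flow: zero input law, ground-truth accuracy, and
           time-reversal symmetry", {
  tx <- with_test_seed(3, matrix(runif(64 * 64), 64, 64))
  const <- image_sequence(list(tx, tx, tx), 1 / 30)
  fl <- compute_flow(const, tile_size = 32, fine_tile = 16,
                     search_radius = 4, fine_radius = 2)
  for (f in fl$fields) expect_true(all(f$vectors == 0))

  sp <- small_scene(seed = 31, amplitude = 3, duration = 3)
  vid <- generate_video(sp)
  fl <- small_flow(vid)
  gt <- attr(vid, "ground_truth")
  err <- vapply(seq_along(fl$fields), function(t) {
    f <- fl$fields[[t]]
    tr <- displacement_at(sp, gt$times[t], f$grid$centers)
    mean(sqrt(rowSums((f$vectors - tr)^2)))
  }, numeric(1))
  expect_lt(max(err), 0.75)

  # reversing frames reverses the field list (per-frame independence)
  short <- image_sequence(vid$frames[1:10], vid$frame_interval)
  rev_seq <- image_sequence(rev(short$frames), short$frame_interval)
  a <- compute_flow(short, reference_index = 2, tile_size = 48,
                    fine_tile = 24, search_radius = 6)
  b <- compute_flow(rev_seq, reference_index = 9, tile_size = 48,
                    fine_tile = 24, search_radius = 6)
  for (t in 1:10)
    expect_identical(a$fields[[t]]$vectors, b$fields[[11 - t]]$vectors)
})

test_that("repeated runs are bit-identical (tie-break determinism)", {
  sp <- small_scene(seed = 8, noise = 0.05, duration = 1.5)
  vid <- generate_video(sp)
  f1 <- small_flow(vid)
  f2 <- small_flow(vid)
  for (t in seq_along(f1$fields))
    expect_identical(f1$fields[[t]]$vectors, f2$fields[[t]]$vectors)
})
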