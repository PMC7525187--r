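# MEA metric layer tested against the generator's ground truth and direct
# arithmetic (Fridericia values via high-precision evaluation, CV under the
# population-SD convention).

test_that("field-potential generator: determinism, spike count, alternans
           intervals", {
  sp <- fp_spec(duration = 10, beat_period = 1, fpd = 0.35, seed = 7)
  t1 <- generate_field_potential(sp)
  t2 <- generate_field_potential(sp)
  expect_identical(t1$voltage, t2$voltage)
  gt <- attr(t1, "ground_truth")
  expect_true(abs(length(gt$spike_times) - 10) <= 1)

  alt <- fp_spec(duration = 12, beat_period = 1, alternans_delta = 0.25,
                 fpd = 0.3, seed = 3)
  gta <- attr(generate_field_potential(alt), "ground_truth")
  iv <- gta$intervals
  expect_equal(iv[seq(2, length(iv), by = 2)],
               rep(0.75, length(iv[seq(2, length(iv), by = 2)])),
               tolerance = 1e-12)
  expect_equal(iv[seq(1, length(iv), by = 2)],
               rep(1.25, length(iv[seq(1, length(iv), by = 2)])),
               tolerance = 1e-12)

  expect_error(fp_spec(beat_period = 0.3, fpd = 0.35), "beat_period > fpd")
  expect_error(fp_spec(alternans_delta = 0.6, beat_period = 1), "alternans")
})

test_that("detect_spikes: recovery within 2 samples, scale invariance, and
           silence on noise-only traces", {
  sp <- fp_spec(duration = 10, beat_period = 1, fpd = 0.35,
                spike_amplitude = 100, noise_sd = 1, seed = 11)
  tr <- generate_field_potential(sp)
  gt <- attr(tr, "ground_truth")
  spikes <- detect_spikes(tr)
  expect_length(spikes, length(gt$spike_times))
  expect_lt(max(abs(spikes - gt$spike_times)), 2 / tr$sampling_rate + 1e-12)

  doubled <- fp_trace(tr$time, 2 * tr$voltage, tr$sampling_rate)
  expect_identical(detect_spikes(doubled), spikes)

  flat <- fp_trace((0:49999) / 5000,
                   with_test_seed(4, rnorm(50000, 0, 0.5)), 5000)
  expect_warning(got <- detect_spikes(flat), "no spikes")
  expect_length(got, 0)
})

test_that("beat_periods arithmetic and undefined status", {
  expect_equal(beat_periods(c(0, 1, 2, 3)),
               list(periods = c(1, 1, 1), mean = 1, sd = 0, status = "ok"))
  bp <- beat_periods(c(0, 0.75, 2.0))
  expect_equal(bp$periods, c(0.75, 1.25))
  expect_equal(bp$mean, 1.0)
  expect_equal(beat_periods(c(1.5))$status, "undefined")

  sp <- fp_spec(duration = 60, beat_period = 1.04, period_jitter_sd = 0.04,
                fpd = 0.35, seed = 21)
  tr <- generate_field_potential(sp)
  m <- beat_periods(detect_spikes(tr))
  expect_lt(abs(m$mean / 1.04 - 1), 0.02)
})

test_that("spike_amplitude: ground-truth height, linearity, zero on
           constants, and window guards", {
  sp <- fp_spec(duration = 8, beat_period = 1, fpd = 0.3,
                spike_amplitude = 100, seed = 5)
  tr <- generate_field_potential(sp)
  gt <- attr(tr, "ground_truth")
  amp <- spike_amplitude(tr, gt$spike_times)
  expect_equal(amp$mean, 100, tolerance = 0.01)

  doubled <- fp_trace(tr$time, 2 * tr$voltage, tr$sampling_rate)
  expect_equal(spike_amplitude(doubled, gt$spike_times)$amplitudes,
               2 * amp$amplitudes, tolerance = 1e-12)

  const <- fp_trace(tr$time, rep(2, length(tr$time)), tr$sampling_rate)
  expect_equal(spike_amplitude(const, gt$spike_times)$mean, 0)

  expect_error(spike_amplitude(tr, gt$spike_times, window = 1.5), "overlaps")
})

test_that("detect_fpd: ground truth recovery, absent bump flagged, and
           monotone in the true FPD", {
  sp <- fp_spec(duration = 20, beat_period = 1, fpd = 0.40, seed = 9)
  tr <- generate_field_potential(sp)
  gt <- attr(tr, "ground_truth")
  fpd <- detect_fpd(tr, gt$spike_times)
  expect_true(all(fpd$detected))
  expect_lt(abs(fpd$mean - 0.40), 2 / tr$sampling_rate + 1e-12)

  nob <- generate_field_potential(
    fp_spec(duration = 20, beat_period = 1, fpd = 0.40, rep_amplitude = 0,
            seed = 9))
  fpd0 <- detect_fpd(nob, attr(nob, "ground_truth")$spike_times)
  expect_false(any(fpd0$detected))
  expect_true(is.na(fpd0$mean))

  est <- vapply(c(0.2, 0.3, 0.4), function(f) {
    tri <- generate_field_potential(
      fp_spec(duration = 20, beat_period = 1, fpd = f, seed = 13))
    detect_fpd(tri, attr(tri, "ground_truth")$spike_times)$mean
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("Fridericia correction: identities, printed-precision values, and
           monotonicity", {
  expect_equal(fridericia_fpdc(0.40, 1.0), 0.40)
  expect_equal(fridericia_fpdc(0.30, 0.512), 0.375, tolerance = 1e-12)
  expect_equal(fridericia_fpdc(0.40, 0.80), 0.40 / 0.80^(1 / 3),
               tolerance = 1e-15)
  # strictly decreasing in beat period, increasing in FPD
  bp <- seq(0.5, 2, by = 0.1)
  expect_true(all(diff(fridericia_fpdc(0.4, bp)) < 0))
  fpd <- seq(0.2, 0.5, by = 0.05)
  expect_true(all(diff(fridericia_fpdc(fpd, 0.8)) > 0))
  expect_error(fridericia_fpdc(-0.1, 1), "positive")
  expect_error(fridericia_fpdc(0.3, 0), "positive")
})

test_that("irregularity: population-SD convention, thresholding, and
           generator calibration", {
  expect_equal(irregularity(rep(1, 10))$cv, 0)
  expect_false(irregularity(rep(1, 10))$arrhythmic)
  alt <- irregularity(rep(c(0.5, 1.5), 10))
  expect_equal(alt$cv, 0.5)
  expect_true(alt$arrhythmic)
  expect_equal(irregularity(c(1, 1))$status, "undefined")

  m_alt <- compute_beat_metrics(generate_field_potential(
    fp_spec(duration = 30, beat_period = 1, alternans_delta = 0.25,
            fpd = 0.3, seed = 17)))
  expect_true(m_alt$arrhythmic)
  m_reg <- compute_beat_metrics(generate_field_potential(
    fp_spec(duration = 30, beat_period = 1, period_jitter_sd = 0.02,
            fpd = 0.3, seed = 17)))
  expect_false(m_reg$arrhythmic)
})

test_that("drug_contrast: identity, ISO-like chronotropy, E4031-like FPDc
           prolongation", {
  base <- compute_beat_metrics(generate_field_potential(
    fp_spec(duration = 40, beat_period = 1.04, fpd = 0.35, seed = 19)))
  same <- drug_contrast(base, base)
  expect_equal(same$beat_period_fold, 1.0)
  expect_equal(same$fpdc_fold, 1.0)
  expect_equal(same$chronotropy, "unchanged")

  iso <- compute_beat_metrics(generate_field_potential(
    fp_spec(duration = 40, beat_period = 0.66, fpd = 0.35 * 0.66 / 1.04,
            seed = 19)))
  con <- drug_contrast(base, iso)
  expect_equal(con$beat_period_fold, 0.66 / 1.04, tolerance = 0.02)
  expect_equal(con$chronotropy, "up")

  e4031 <- compute_beat_metrics(generate_field_potential(
    fp_spec(duration = 40, beat_period = 1.04, fpd = 0.50, seed = 19)))
  con2 <- drug_contrast(base, e4031)
  expect_equal(con2$fpdc_fold, 0.50 / 0.35, tolerance = 0.02)
  expect_equal(con2$fpdc_direction, "prolonged")
})
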