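test_that("elbow velocity subtracts the upper-arm channel and rest bias", {
  t <- seq(0, 19.99, by = 0.01)
  fore <- 100 * sin(2 * pi * 0.5 * t)

  tr <- motion_trace(100, t, fore, rep(0, length(t)))
  expect_equal(elbow_velocity(tr)$values, fore)

  tr2 <- motion_trace(100, t, fore, fore)
  expect_equal(elbow_velocity(tr2)$values, rep(0, length(t)))

  # constant gyro offset removed by a 1-s rest window
  rest <- rep(0, 100)
  fore3 <- c(rest, fore)
  t3 <- seq(0, by = 0.01, length.out = length(fore3))
  tr_clean <- motion_trace(100, t3, fore3, rep(0, length(fore3)))
  tr_biased <- motion_trace(100, t3, fore3 + 5, rep(0, length(fore3)))
  expect_equal(elbow_velocity(tr_biased, rest_window = 1)$values,
               elbow_velocity(tr_clean, rest_window = 1)$values,
               tolerance = 1e-12)

  expect_error(motion_trace(100, t, fore[-1], fore), "equal length")
})

test_that("cycle segmentation recovers closed-form sinusoid geometry", {
  s <- sinusoid_series(A = 200, f = 0.5)
  cyc <- segment_cycles(s)
  expect_equal(nrow(cyc), 10)
  expect_equal(cyc$velocity_range, rep(400, 10), tolerance = 1e-6)
  expect_equal(cyc$angle_range, rep(200 / (pi * 0.5), 10), tolerance = 0.02)
  expect_equal(cyc$rise_time, rep(0.5, 10), tolerance = 0.03)
  # half-open, ordered, non-overlapping intervals
  expect_true(all(cyc$end > cyc$start))
  expect_true(all(head(cyc$end, -1) <= tail(cyc$start, -1) + 1))
})

test_that("degenerate series yield zero cycles, not errors", {
  flat <- angular_velocity_series(rep(0, 2000), 100)
  expect_equal(nrow(segment_cycles(flat)), 0)
  set.seed(1)
  noise <- angular_velocity_series(rnorm(2000, 0, 2), 100)
  expect_equal(nrow(segment_cycles(noise)), 0)
  expect_error(segment_cycles(angular_velocity_series(rep(1, 50), 100)),
               "1 s")
})

test_that("segment inertia follows the anthropometric model", {
  expect_equal(estimate_inertia(100, 100,
                                inertia_model(0.022, 0.254, 0.827)),
               2.2 * (0.254 * 0.827)^2, tolerance = 1e-12)
  base <- estimate_inertia(70, 170)
  expect_equal(estimate_inertia(140, 170), 2 * base)
  expect_equal(estimate_inertia(70, 340), 4 * base)
  expect_error(estimate_inertia(-1, 170), "positive")
  expect_error(inertia_model(1.5, 0.2, 0.8), "\\(0, 1\\)")
})

test_that("the eight outcomes match closed forms on a pure sinusoid", {
  s <- sinusoid_series(A = 200, f = 0.5)
  cyc <- segment_cycles(s)
  p <- compute_uef_parameters(s, cyc, mass = 100, height = 100)
  expect_equal(p$speed, 400, tolerance = 0.02)
  expect_equal(p$flexibility, 200 / (pi * 0.5), tolerance = 0.02)
  expect_equal(p$power, (4 * pi * 0.5 * 200) * (2 * 200), tolerance = 0.02)
  expect_equal(p$rise_time, 0.5, tolerance = 0.02)
  expect_equal(p$speed_variability, 0, tolerance = 1e-6)
  expect_equal(p$speed_reduction, 0, tolerance = 1e-6)
  expect_equal(p$flexion_number, 10)
  # moment: I * peak acceleration (2 pi f A, converted to rad/s^2)
  I <- estimate_inertia(100, 100)
  expect_equal(p$moment, I * 2 * pi * 0.5 * 200 * pi / 180, tolerance = 0.02)
})

test_that("fatigue ramp with 0.8 last/first window amplitude ratio gives -20%", {
  fs <- 100; f <- 1
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  # per-cycle amplitude linear through the 5-s window midpoints: ratio of
  # last-window mean to first-window mean is exactly 0.8
  amp_of <- function(tt) 300 * (1 - 0.2 * (tt - 2.5) / 15)
  cyc_mid <- (floor(t * f) + 0.5) / f
  v <- amp_of(cyc_mid) * sin(2 * pi * f * t)
  p <- compute_uef_parameters(s <- angular_velocity_series(v, fs),
                              segment_cycles(s))
  expect_equal(p$speed_reduction, -20, tolerance = 0.02)
})

test_that("outcomes scale correctly under velocity rescaling", {
  s <- sinusoid_series(A = 250, f = 0.8)
  p1 <- compute_uef_parameters(s, segment_cycles(s), 70, 165)
  for (c in c(0.5, 2, 3.7)) {
    sc <- angular_velocity_series(c * s$values, s$sampling_rate)
    p2 <- compute_uef_parameters(sc, segment_cycles(sc), 70, 165)
    expect_equal(p2$speed, c * p1$speed, tolerance = 1e-6)
    expect_equal(p2$flexibility, c * p1$flexibility, tolerance = 1e-6)
    # argmax positions can hop one sample under rescaling round-off, so
    # the acceleration-dependent quantities get a small tolerance
    expect_equal(p2$power, c^2 * p1$power, tolerance = 1e-3)
    expect_equal(p2$speed_variability, p1$speed_variability,
                 tolerance = 1e-3)
    expect_equal(p2$rise_time, p1$rise_time, tolerance = 0.02)
    expect_equal(p2$flexion_number, p1$flexion_number)
  }
})

test_that("time reversal preserves symmetric cycle-train outcomes", {
  # a cosine train is (sample-shift) invariant under time reversal over a
  # whole number of periods, so segmentation sees the same cycle geometry
  t <- seq(0, 19.99, by = 0.01)
  s <- angular_velocity_series(200 * cos(2 * pi * 0.5 * t), 100)
  sr <- angular_velocity_series(rev(s$values), s$sampling_rate)
  p1 <- compute_uef_parameters(s, segment_cycles(s))
  p2 <- compute_uef_parameters(sr, segment_cycles(sr))
  expect_equal(p2$speed, p1$speed, tolerance = 0.01)
  expect_equal(p2$flexibility, p1$flexibility, tolerance = 0.01)
  expect_equal(p2$power, p1$power, tolerance = 0.01)
  expect_equal(p2$flexion_number, p1$flexion_number)
})

test_that("extraction is robust to low-level sensor noise", {
  s <- sinusoid_series(A = 200, f = 1)
  p0 <- compute_uef_parameters(s, segment_cycles(s))
  set.seed(3)
  sn <- angular_velocity_series(s$values + rnorm(length(s$values), 0, 2),
                                s$sampling_rate)
  pn <- compute_uef_parameters(sn, segment_cycles(sn))
  expect_lt(abs(pn$speed - p0$speed) / p0$speed, 0.03)
  expect_equal(pn$flexion_number, p0$flexion_number)
})

test_that("fewer than two cycles flags variability and reduction missing", {
  t <- seq(0, 1.99, by = 0.01)
  s <- angular_velocity_series(200 * sin(2 * pi * 0.5 * t), 100)
  cyc <- segment_cycles(s)
  expect_equal(nrow(cyc), 1)
  p <- compute_uef_parameters(s, cyc)
  expect_true(is.na(p$speed_variability))
  expect_true(is.na(p$speed_reduction))
  expect_equal(p$speed, 400, tolerance = 0.02)
  expect_equal(p$flexion_number, 1)
})
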