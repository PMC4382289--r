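test_that("band coverage counts grid points inside one standard deviation", {
  pct <- seq(0, 100, length.out = 101)
  band <- reference_band(sin(pct / 10), rep(0.5, 101), pct)
  # curve identical to the band mean: full coverage
  expect_equal(band_coverage(band$mean, band), 100)
  # curve above mean + SD on exactly half the interior grid
  curve <- band$mean
  curve[1:50] <- curve[1:50] + 1    # 50 of 101 points pushed outside
  expect_equal(band_coverage(curve, band), 100 * 51 / 101)
  # zero-SD band still counts the boundary as inside
  band0 <- reference_band(rep(2, 101), rep(0, 101), pct)
  expect_equal(band_coverage(rep(2, 101), band0), 100)
  expect_error(band_coverage(rep(0, 50), band), "different grids")
  expect_error(reference_band(rep(0, 101), rep(-1, 101)), "non-negative")
})

test_that("band coverage shrinks monotonically with the SD envelope", {
  set.seed(14)
  pct <- seq(0, 100, length.out = 101)
  curve <- sin(pct / 7) + rnorm(101, 0, 0.3)
  cov <- vapply(c(2, 1, 0.5, 0.25, 0.1), function(sd)
    band_coverage(curve, reference_band(sin(pct / 7), rep(sd, 101), pct)),
    numeric(1))
  expect_true(all(diff(cov) <= 0))
  expect_true(all(cov >= 0 & cov <= 100))
})

test_that("Teager-Kaiser onsets recover constructed bursts and reject noise", {
  fx <- generate_fixtures(seed = 3)
  # constant signal: psi is identically zero, no onsets
  expect_equal(nrow(teager_kaiser_onsets(rep(2, 1000), fs = 1500)), 0)
  expect_error(teager_kaiser_onsets(c(1, 2), fs = 1500), "3 samples")
  # pure Gaussian baseline noise at six SDs: no detections
  set.seed(31)
  for (i in 1:5) {
    noise <- rnorm(3000, 0, 0.01)
    expect_equal(nrow(teager_kaiser_onsets(noise, fs = 1500, n_sd = 6,
                                           baseline = 1:1000)), 0)
  }
  # amplified bursts at known times are detected and overlap the truth
  on <- teager_kaiser_onsets(fx$emg$signal, fs = fx$emg$fs, n_sd = 6)
  expect_equal(nrow(on), nrow(fx$emg$bursts))
  for (b in seq_len(nrow(fx$emg$bursts))) {
    expect_lt(abs(on$onset[b] - fx$emg$bursts$on[b]), 0.05)
    expect_lt(abs(on$offset[b] - fx$emg$bursts$off[b]), 0.05)
  }
})

test_that("mean-stride extraction ignores the first two strides", {
  fx <- generate_fixtures(seed = 2)
  tr <- fx$trajectory
  mc <- extract_mean_stride(tr, leg = "r", channels = c("q_hip_r", "com_y"))
  # identical synthetic strides: the mean equals the generating curve
  expected <- (30 * sin(2 * pi * mc$pct / 100 + 0.3) + 5) * pi / 180
  expect_equal(unname(mc$curves[, "q_hip_r"]), expected, tolerance = 1e-3)
  expect_equal(mc$stride_time, 1.1, tolerance = 1e-6)
  expect_equal(mc$stride_length, 1.5 * 1.1, tolerance = 1e-6)

  # corrupt the first two strides only: the mean must not change
  tr2 <- tr
  early <- tr2$samples$t < 2.2
  tr2$samples$q_hip_r[early] <- tr2$samples$q_hip_r[early] + 5
  mc2 <- extract_mean_stride(tr2, leg = "r", channels = "q_hip_r")
  expect_equal(mc2$curves[, "q_hip_r"], mc$curves[, "q_hip_r"],
               tolerance = 1e-9)

  # too few strides is an error naming the counts
  short <- tr
  short$events <- tr$events[tr$events$time < 2.5, ]
  short$samples <- tr$samples[tr$samples$t < 2.5, ]
  expect_error(extract_mean_stride(short), "strides")
})

test_that("stride time averages over included strides of unequal length", {
  # constructed fixture: strides alternating between T and 1.2 T
  Ts <- rep(c(1.0, 1.2), 5)
  hs <- cumsum(c(0.5, Ts))
  tt <- seq(0, max(hs) + 0.5, by = 0.01)
  s <- data.frame(t = tt, com_x = 1.4 * tt, x = sin(tt))
  ev <- data.frame(time = hs, leg = "r", com_x = 1.4 * hs)
  tr <- make_traj(s, ev, duration = max(tt))
  mc <- extract_mean_stride(tr, leg = "r", channels = "x")
  expect_equal(mc$stride_time, mean(rep(c(1.2, 1.0), 4)), tolerance = 1e-9)
  expect_equal(mc$n_strides, 8)
})

test_that("metabolic summaries normalize to unloaded body mass", {
  tt <- seq(0, 10, by = 0.01)
  s <- data.frame(t = tt, met_total = 320, com_x = 1.4 * tt)
  ev <- data.frame(time = 1:9, leg = rep(c("r", "l"), 5)[1:9],
                   com_x = 1.4 * (1:9))
  tr <- make_traj(s, ev, m_body = 80, m_back = 0)
  ms <- metabolic_summary(tr)
  expect_equal(ms$power_per_kg, 4.0)
  # percent change against a reference
  expect_equal(metabolic_summary(tr, reference = 4.0)$pct_change, 0)
  expect_equal(metabolic_summary(make_traj(
    data.frame(t = tt, met_total = 400, com_x = 1.4 * tt), ev),
    reference = 4.0)$pct_change, 25)
  # a loaded trial still divides by the unloaded 80 kg
  trl <- make_traj(s, ev, m_body = 80, m_back = 32)
  expect_equal(metabolic_summary(trl)$power_per_kg, 4.0)
})

test_that("fixtures are deterministic and self-consistent", {
  f1 <- generate_fixtures(seed = 42)
  f2 <- generate_fixtures(seed = 42)
  expect_identical(f1$emg$signal, f2$emg$signal)
  expect_identical(f1$bands$hip$mean, f2$bands$hip$mean)
  expect_identical(f1$trajectory$samples, f2$trajectory$samples)
  f3 <- generate_fixtures(seed = 43)
  expect_false(identical(f1$emg$signal, f3$emg$signal))
  # a band always fully covers its own mean curve
  for (b in f1$bands) expect_equal(band_coverage(b$mean, b), 100)
  # mean-stride extraction is idempotent on the periodic trajectory
  m1 <- extract_mean_stride(f1$trajectory, channels = "q_knee_r")
  expect_equal(dim(m1$curves), c(101, 1))
  expect_true(all(is.finite(m1$curves)))
})
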