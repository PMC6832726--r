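test_that("step and stride frequency are recovered from clean gait", {
  ep <- aligned_episode(duration_s = 10, f_stride = 0.9, seed = 1)
  fr <- detect_frequencies(ep)
  expect_true(fr$valid)
  expect_equal(fr$f_step, 1.8, tolerance = 0.02)
  expect_equal(fr$f_stride, 0.9, tolerance = 0.005)
  expect_equal(fr$stride_time, 1 / 0.9, tolerance = 0.005)
})

test_that("stride frequency stays within 5% under heavy phase jitter", {
  ep <- aligned_episode(duration_s = 10, f_stride = 0.9, jitter = 0.3,
                        seed = 21)
  fr <- detect_frequencies(ep)
  expect_true(fr$valid)
  expect_equal(fr$f_stride, 0.9, tolerance = 0.05)
})

test_that("pure white noise is flagged as non-gait", {
  set.seed(42)
  for (i in 1:5) {
    ep <- one_axis_epoch(rnorm(1000, 0, 0.1), axis = "vt")
    ep$samples[, 3] <- rnorm(1000, 0, 0.1)
    expect_false(detect_frequencies(ep)$valid)
  }
})

test_that("double integration reproduces the closed-form sinusoid excursion", {
  # acc = A sin(2 pi f t), A = 1 m/s^2, f = 2 Hz -> displacement amplitude
  # A/(2 pi f)^2 = 0.006333 m, per-step peak-to-peak h = 0.012666 m
  fs <- 100
  t <- (0:999) / fs
  acc_g <- sin(2 * pi * 2 * t) / gaitquality:::G_TO_MS2
  ep <- one_axis_epoch(acc_g, fs = fs, axis = "vt")
  freqs <- list(f_step = 2, f_stride = 1, stride_time = 1, valid = TRUE)
  res <- walking_speed_and_stride_length(ep, freqs, leg_length = 0.9)
  # sampling grid does not hit the sinusoid's exact extrema: ~0.2% low
  expect_equal(res$h, 2 * 1 / (2 * pi * 2)^2, tolerance = 0.01)
})

test_that("the inverted-pendulum chain matches the hand-computed values", {
  # step length for h = 0.02, leg 0.9: 2 sqrt(0.036 - 0.0004) = 0.37736 m
  # realised through a VT sinusoid whose excursion gives exactly h = 0.02
  fs <- 100
  f_step <- 2
  t <- (0:999) / fs
  A <- 0.02 / 2 * (2 * pi * f_step)^2          # m/s^2 amplitude for h = 0.02
  ep <- one_axis_epoch(A * sin(2 * pi * f_step * t) / gaitquality:::G_TO_MS2,
                       fs = fs, axis = "vt")
  freqs <- list(f_step = f_step, f_stride = 1, stride_time = 1, valid = TRUE)
  res <- walking_speed_and_stride_length(ep, freqs, leg_length = 0.9)
  expect_equal(res$walking_speed, 0.37736 * f_step, tolerance = 0.02)
  expect_equal(res$stride_length, 2 * 0.37736, tolerance = 0.02)
})

test_that("non-physical excursions and missing leg length are handled", {
  fs <- 100
  t <- (0:999) / fs
  # slow (0.5 Hz) steps so a > 0.9 m excursion stays inside +/-6 g
  big <- 0.95 / 2 * (2 * pi * 0.5)^2
  ep <- one_axis_epoch(big * sin(2 * pi * 0.5 * t) / gaitquality:::G_TO_MS2,
                       fs = fs, axis = "vt")
  freqs <- list(f_step = 0.5, f_stride = 0.25, stride_time = 4, valid = TRUE)
  expect_error(suppressMessages(
    walking_speed_and_stride_length(ep, freqs, leg_length = 0.9)),
    "non-physical")
  ok <- one_axis_epoch(sin(2 * pi * 2 * t) / gaitquality:::G_TO_MS2,
                       fs = fs, axis = "vt")
  f2 <- list(f_step = 2, f_stride = 1, stride_time = 1, valid = TRUE)
  expect_warning(walking_speed_and_stride_length(ok, f2, leg_length = NULL),
                 "default")
})

test_that("dispersion features match sinusoid moments and noise targets", {
  z <- one_axis_epoch(rep(0, 1000), axis = "ap")
  d0 <- dispersion_features(z, feature_config(units = "g"))
  expect_equal(d0$sd_ap, 0, ignore_attr = TRUE)
  expect_equal(d0$range_ap, 0, ignore_attr = TRUE)

  A <- 0.4
  t <- (0:9999) / 100
  ds <- dispersion_features(one_axis_epoch(A * sin(2 * pi * 1 * t), axis = "ml"),
                            feature_config(units = "g"))
  expect_equal(ds$sd_ml, A / sqrt(2), tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(ds$range_ml, 2 * A, tolerance = 1e-3, ignore_attr = TRUE)

  set.seed(9)
  dn <- dispersion_features(one_axis_epoch(rnorm(5000, 0, 0.1), axis = "vt"),
                            feature_config(units = "g"))
  expect_equal(dn$sd_vt, 0.1, tolerance = 0.03, ignore_attr = TRUE)

  # unit conversion: m/s^2 output is the g output scaled by 9.80665
  dm <- dispersion_features(z, feature_config(units = "ms2"))
  expect_equal(dm$sd_ap, d0$sd_ap * 9.80665, ignore_attr = TRUE)
})

test_that("stride regularity is 1 for periodic gait and ~0 for noise", {
  ep <- aligned_episode(duration_s = 10, f_stride = 1, seed = 1)
  reg <- stride_regularity(ep, 1)
  expect_gte(reg$stride_autocorr_vt, 0.999)
  expect_gte(reg$stride_autocorr_ap, 0.999)

  set.seed(11)
  noise <- accel_episode(matrix(rnorm(3000, 0, 0.1), ncol = 3), 100,
                         aligned = TRUE)
  regn <- stride_regularity(noise, 1)
  expect_lt(abs(regn$stride_autocorr_vt), 0.1)

  # stride lag beyond half the epoch: not computable
  expect_null(stride_regularity(ep, 6))
})

test_that("regularity agrees with the brute-force autocovariance oracle", {
  ep <- aligned_episode(duration_s = 10, f_stride = 1, jitter = 0.3, seed = 3)
  lag0 <- 100
  lags <- seq(round(0.9 * lag0), round(1.1 * lag0))
  ours <- stride_regularity(ep, 1)$stride_autocorr_vt
  oracle <- max(vapply(lags, function(k)
    oracle_unbiased_autocorr(ep$samples[, 1], k), numeric(1)))
  expect_equal(ours, min(1, oracle), tolerance = 1e-10, ignore_attr = TRUE)
})
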