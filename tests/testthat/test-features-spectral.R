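make_cosines <- function(freqs_amps, duration_s = 10, fs = 100) {
  t <- (0:(duration_s * fs - 1)) / fs
  Reduce(`+`, lapply(seq_len(nrow(freqs_amps)), function(i)
    freqs_amps[i, 2] * cos(2 * pi * freqs_amps[i, 1] * t)))
}

test_that("dominant-peak amplitude captures single and split peaks", {
  x <- make_cosines(cbind(2, 0.5))
  sp <- suppressWarnings(spectral_peak_features(one_axis_epoch(x, axis = "vt")))
  expect_gte(sp$dominant_amp_vt, 0.95)

  two <- make_cosines(rbind(c(1.5, 0.5), c(3.1, 0.5)))
  sp2 <- suppressWarnings(spectral_peak_features(one_axis_epoch(two, axis = "ap")))
  expect_equal(sp2$dominant_amp_ap, 0.5, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("peak power fraction matches a direct periodogram oracle", {
  set.seed(5)
  t <- (0:1999) / 100
  x <- 0.4 * cos(2 * pi * 2 * t) + rnorm(2000, 0, 0.1)
  sp <- suppressWarnings(spectral_peak_features(one_axis_epoch(x, axis = "vt")))
  oracle <- oracle_periodogram_fraction(x, 100, 1.8, 2.2)
  expect_equal(sp$dominant_amp_vt, oracle, tolerance = 0.05,
               ignore_attr = TRUE)
  # the cosine sits in one Welch bin: half-power width is that bin
  expect_equal(sp$dominant_width_vt, 0.2, ignore_attr = TRUE)
})

test_that("a powerless axis reports the full band as width, with a warning", {
  const <- one_axis_epoch(rep(0, 1000), axis = "vt")
  w <- capture_warnings(sp <- spectral_peak_features(const))
  expect_true(any(grepl("flat", w)))
  expect_equal(sp$dominant_width_ml, 50, ignore_attr = TRUE)
  expect_true(is.na(sp$dominant_amp_ml))
})

test_that("index of harmonicity matches Parseval on known amplitudes", {
  freqs <- list(f_step = 2, f_stride = 1, stride_time = 1, valid = TRUE)
  # single harmonic at the fundamental: IH = 1
  one <- one_axis_epoch(make_cosines(cbind(2, 0.3)), axis = "vt")
  expect_equal(index_of_harmonicity(one, freqs)$ih_vt, 1, tolerance = 1e-6)
  # equal power at f0 and 2 f0: IH = 0.5
  half <- one_axis_epoch(make_cosines(rbind(c(2, 0.3), c(4, 0.3))), axis = "vt")
  expect_equal(index_of_harmonicity(half, freqs)$ih_vt, 0.5, tolerance = 1e-6)
  # general amplitudes: IH = a1^2 / sum(ak^2)
  a <- c(0.3, 0.15, 0.08, 0.05)
  multi <- one_axis_epoch(make_cosines(cbind(1 * (1:4), a)), axis = "ml")
  expect_equal(index_of_harmonicity(multi, freqs)$ih_ml,
               a[1]^2 / sum(a^2), tolerance = 1e-6)
  # zero harmonic power: flagged as NA
  flat <- one_axis_epoch(rep(0, 1000), axis = "vt")
  expect_true(is.na(index_of_harmonicity(flat, freqs)$ih_vt))
})

test_that("harmonic ratio follows the even/odd amplitude definition", {
  freqs <- list(f_step = 2, f_stride = 1, stride_time = 1, valid = TRUE)
  # VT: even 0.5 + 1.5 = 2.0, odd 0.4 + 0.6 = 1.0 -> HR = 2.0
  x <- make_cosines(rbind(c(1, 0.4), c(2, 0.5), c(3, 0.6), c(4, 1.5)))
  hr <- suppressWarnings(harmonic_ratio(one_axis_epoch(x, axis = "vt"), freqs))
  expect_equal(hr$hr_vt, 2.0, tolerance = 1e-6)
  # ML inverts the ratio: odd/even
  hrm <- suppressWarnings(harmonic_ratio(one_axis_epoch(x, axis = "ml"), freqs))
  expect_equal(hrm$hr_ml, 0.5, tolerance = 1e-6)
  # four odd harmonics at 0.1 each, four even at 0.3 each -> HR = 3.0
  y <- make_cosines(cbind(1:8, rep(c(0.1, 0.3), 4)))
  hra <- suppressWarnings(harmonic_ratio(one_axis_epoch(y, axis = "ap"), freqs))
  expect_equal(hra$hr_ap, 3.0, tolerance = 1e-6)
  # pure cosine at the 2nd stride harmonic: zero odd power -> capped
  pure <- one_axis_epoch(make_cosines(cbind(2, 0.3)), axis = "vt")
  w <- capture_warnings(hrc <- harmonic_ratio(pure, freqs))
  expect_true(any(grepl("capping", w)))
  expect_equal(hrc$hr_vt, 100)
})

test_that("composite score is linear in standardized inputs", {
  w <- composite_weights()
  feats <- list(stride_autocorr_vt = 0, dominant_amp_vt = 0, rms = 0,
                ih_vt = 0)
  expect_equal(composite_score(feats, w), 0)

  w1 <- composite_weights(weights = c(regularity = 1, step_power = 0,
                                      rms = 0, harmonicity = 0))
  feats$stride_autocorr_vt <- 1.7
  expect_equal(composite_score(feats, w1), 1.7)
  feats$stride_autocorr_vt <- 3.4
  expect_equal(composite_score(feats, w1), 2 * 1.7)

  # standardization and missing-input propagation
  ws <- composite_weights(means = c(regularity = 0.5, step_power = 0,
                                    rms = 0, harmonicity = 0),
                          sds = c(regularity = 0.2, step_power = 1,
                                  rms = 1, harmonicity = 1))
  feats2 <- list(stride_autocorr_vt = 0.7, dominant_amp_vt = 0, rms = 0,
                 ih_vt = 0)
  expect_equal(composite_score(feats2, ws), (0.7 - 0.5) / 0.2)
  feats2$ih_vt <- NA_real_
  expect_true(is.na(composite_score(feats2, ws)))
})
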