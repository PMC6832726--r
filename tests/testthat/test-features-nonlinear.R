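test_that("sample entropy handles degenerate and near-deterministic series", {
  const <- one_axis_epoch(rep(0.3, 400), axis = "ml")
  expect_equal(sample_entropy(const, r = 0.1)$sampen_ml, 0)

  t <- (0:999) / 100
  slow <- one_axis_epoch(0.5 * sin(2 * pi * 0.5 * t), axis = "ml")
  expect_lt(sample_entropy(slow)$sampen_ml, 0.3)
})

test_that("sample entropy equals the O(N^2) template-counting oracle", {
  set.seed(31)
  x <- rnorm(1000)
  ep <- one_axis_epoch(x, axis = "ml")
  r <- 0.2 * sd(x)
  expect_equal(sample_entropy(ep)$sampen_ml, oracle_sampen(x, 2L, r),
               tolerance = 1e-9)
  # and for gait-like data with jitter
  epg <- aligned_episode(duration_s = 10, f_stride = 1, jitter = 0.4,
                         noise = 0.02, seed = 13)
  xg <- epg$samples[1:1000, 2]
  expect_equal(sample_entropy(one_axis_epoch(xg, axis = "ml"))$sampen_ml,
               oracle_sampen(xg, 2L, 0.2 * sd(xg)), tolerance = 1e-9)
})

test_that("local divergence rate is ~0 on a limit cycle", {
  ep <- aligned_episode(duration_s = 10, f_stride = 1, seed = 1)
  lde <- local_divergence_rate(ep, 1)
  expect_lt(abs(lde$lde_vt), 0.1)
  expect_lt(abs(lde$lde_ap), 0.1)
})

test_that("local divergence rate matches the brute-force oracle to 1e-6", {
  ep <- aligned_episode(duration_s = 10, f_stride = 1, jitter = 0.3,
                        noise = 0.02, seed = 17)
  st <- 1
  ours <- local_divergence_rate(ep, st)
  expect_equal(ours$lde_vt, oracle_lde(ep$samples[, 1], 100, st),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(ours$lde_ap, oracle_lde(ep$samples[, 3], 100, st),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("too-short epochs are not embedded", {
  short <- one_axis_epoch(rnorm(120), axis = "vt")
  expect_null(local_divergence_rate(short, 1))
})

test_that("regularity, stability and entropy order a pure phase-jitter ladder", {
  # noise-free so the jitter knob is the only source of irregularity;
  # SampEn responds from the periodic baseline but saturates at high
  # jitter, so only the baseline comparison is strict for it
  lv <- lapply(c(0, 0.2, 0.5), function(j)
    aligned_episode(duration_s = 10, f_stride = 1, jitter = j,
                    noise = 0, seed = 23))
  reg <- vapply(lv, function(e)
    stride_regularity(e, 1)$stride_autocorr_vt, numeric(1))
  lde <- vapply(lv, function(e)
    local_divergence_rate(e, 1)$lde_vt, numeric(1))
  se <- vapply(lv, function(e) sample_entropy(e)$sampen_ml, numeric(1))
  expect_true(all(diff(reg) < 0))
  expect_true(all(diff(lde) > 0))
  expect_true(all(se[2:3] > se[1]))
})

test_that("bounded characteristics respect their documented ranges", {
  # a spread of jitter/noise/asymmetry settings, one seed per case
  cases <- expand.grid(jitter = c(0, 0.3), noise = c(0.01, 0.05),
                       f_stride = c(0.8, 1.0))
  for (i in seq_len(nrow(cases))) {
    ep <- aligned_episode(duration_s = 10, f_stride = cases$f_stride[i],
                          jitter = cases$jitter[i], noise = cases$noise[i],
                          seed = 100 + i)
    fr <- detect_frequencies(ep)
    expect_true(fr$valid)
    reg <- stride_regularity(ep, fr$stride_time)
    expect_true(all(abs(unlist(reg)) <= 1))
    ih <- index_of_harmonicity(ep, fr)
    expect_true(all(unlist(ih) >= 0 & unlist(ih) <= 1))
    sp <- spectral_peak_features(ep)
    amps <- unlist(sp[c("dominant_amp_vt", "dominant_amp_ml",
                        "dominant_amp_ap")])
    expect_true(all(amps >= 0 & amps <= 1))
    hr <- harmonic_ratio(ep, fr)
    expect_true(all(unlist(hr) > 0 & unlist(hr) <= 100))
    expect_gte(sample_entropy(ep)$sampen_ml, 0)
  }
})
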