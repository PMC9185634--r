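test_that("sliding RMS reproduces constant, sinusoidal and stochastic levels", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, 1 / fs)
  expect_equal(rms_envelope(ts_channel(rep(-3, 5000), fs))$samples,
               rep(3, 5000))
  env <- rms_envelope(ts_channel(2 * sin(2 * pi * 80 * t), fs))  # 8 cycles/window
  i <- 500:9500
  expect_lt(max(abs(env$samples[i] - 2 / sqrt(2))) / (2 / sqrt(2)), 0.01)
  set.seed(31)
  envn <- rms_envelope(ts_channel(rnorm(length(t), 0, 1.4), fs))
  expect_lt(abs(mean(envn$samples) - 1.4) / 1.4, 0.03)
  expect_error(rms_envelope(ts_channel(rnorm(100), 10), window_ms = 100),
               class = "ripsync_validation_error")
})

test_that("MVC reference takes the mean around the maximum, maximized across efforts", {
  fs <- 1000
  expect_equal(mvc_reference(list(ts_channel(rep(2.5, 3000), fs)))$reference_value,
               2.5)
  # flat-topped efforts wider than the window: reference = max of plateaus
  seg <- function(a) ts_channel(c(seq(0, a, length.out = 500),
                                  rep(a, 2000),
                                  seq(a, 0, length.out = 500)), fs)
  ref <- mvc_reference(list(seg(1), seg(2), seg(1.5)))
  expect_equal(ref$reference_value, 2, tolerance = 1e-6)
  expect_length(ref$trial_peaks, 3L)
  # triangular pulse: closed-form mean of the RMS ramp around the peak
  a <- 4; n_half <- 1000                       # 1-s ramps, slope a per second
  tri <- ts_channel(c(seq(0, a, length.out = n_half + 1)[-1],
                      seq(a, 0, length.out = n_half + 1)[-1]), fs)
  ref_tri <- mvc_reference(list(tri))$reference_value
  # RMS of a linear ramp x(t)=a*t over +-w/2 around the apex, then averaged
  # over the centered 100 ms window, computed by numeric quadrature oracle
  # signal around the apex at t = 1 s is x(t) = a * (1 - |t - 1|)
  w <- 0.1
  rms_at <- function(tc) {
    g <- function(u) (a * (1 - abs(u + tc - 1)))^2
    sqrt(stats::integrate(g, -w / 2, w / 2)$value / w)
  }
  oracle <- mean(vapply(seq(1 - w / 2, 1 + w / 2, length.out = 201), rms_at,
                        numeric(1)))
  expect_equal(ref_tri, oracle, tolerance = 0.01)
  expect_error(mvc_reference(list()), class = "ripsync_validation_error")
})

test_that("%MVC normalization is a pure ratio and scale-invariant", {
  fs <- 1000
  ref <- mvc_reference(list(ts_channel(rep(2, 2000), fs)))
  half <- normalize_to_mvc(ts_channel(rep(1, 1000), fs), ref)
  expect_equal(half$samples, rep(50, 1000))
  full <- normalize_to_mvc(ts_channel(rep(2, 1000), fs), ref)
  expect_equal(full$samples, rep(100, 1000))
  # multiplying raw EMG and MVC by one constant leaves %MVC unchanged
  set.seed(32)
  raw <- rnorm(4000)
  seg <- list(ts_channel(3 * abs(rnorm(3000)), fs))
  pct1 <- normalize_to_mvc(rms_envelope(ts_channel(raw, fs)),
                           mvc_reference(seg))$samples
  seg2 <- list(ts_channel(seg[[1]]$samples * 7, fs))
  pct2 <- normalize_to_mvc(rms_envelope(ts_channel(raw * 7, fs)),
                           mvc_reference(seg2))$samples
  expect_equal(pct1, pct2, tolerance = 1e-10)
})

test_that("median frequency matches line spectra and flat bands", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, 1 / fs)
  mf_tone <- median_frequency(ts_channel(sin(2 * pi * 80 * t), fs))
  expect_lt(abs(mf_tone - 80), 1)
  # equal-power two-line spectrum: median falls between the lines
  mf_two <- median_frequency(ts_channel(sin(2 * pi * 40 * t) +
                                          sin(2 * pi * 120 * t), fs))
  expect_gt(mf_two, 40); expect_lt(mf_two, 120)
  # flat band [20, 140] -> median at 80, Monte-Carlo over seeds
  set.seed(33)
  mfs <- replicate(10, {
    x <- ripsync:::shaped_emg_noise(40000, fs, 80, 1)
    median_frequency(ts_channel(x, fs))
  })
  expect_lt(abs(mean(mfs) - 80), 2)
  # amplitude scaling leaves the median untouched
  x <- ripsync:::shaped_emg_noise(20000, fs, 70, 1)
  expect_equal(median_frequency(ts_channel(x, fs)),
               median_frequency(ts_channel(10 * x, fs)), tolerance = 1e-9)
  expect_error(median_frequency(ts_channel(rep(0, 5000), fs)),
               class = "ripsync_validation_error")
})

test_that("decile features partition trials and recover imposed ramps", {
  set.seed(34)
  cfg <- study_config(trial_length_s = 120, rest_length_s = 2, channels = "emg",
                      emg_amp_ramp = 0.4, emg_mf_ramp = -10,
                      between_subject_sd = 0)
  g <- quiet_butter(gen_recording(cfg, "S01"))
  feats <- quiet_butter(emg_features_by_decile(g$recording, "biceps"))
  expect_identical(nrow(feats), 30L)                 # 3 trials x 10 divisions
  expect_identical(sort(unique(feats$division)), 1:10)
  base <- dplyr::filter(feats, .data$trial == "Baseline")
  # imposed within-trial amplitude rise: increasing decile means
  expect_gt(stats::cor(base$division, base$amplitude_pct_mvc,
                       method = "spearman"), 0.9)
  # imposed median-frequency fall: decreasing decile means
  expect_lt(stats::cor(base$division, base$median_freq_hz,
                       method = "spearman"), -0.9)
})
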