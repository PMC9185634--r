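test_that("FIR band-pass passes the breathing band and rejects DC", {
  fs <- 200
  t <- seq(0, 300 - 1 / fs, 1 / fs)
  ch <- ts_channel(sin(2 * pi * 0.25 * t), fs)
  out <- fir_bandpass(ch)
  i <- seq(40 * fs, 260 * fs)   # steady state, away from edge transients
  expect_gt(stats::cor(out$samples[i], ch$samples[i]), 0.999)
  # constant input -> exactly zero output
  const <- ts_channel(rep(7.5, length(t)), fs)
  expect_lt(max(abs(fir_bandpass(const)$samples)), 1e-8 * 7.5)
  expect_error(fir_bandpass(ts_channel(rnorm(50), fs)),
               class = "ripsync_validation_error")
  expect_error(fir_bandpass(ch, 0.45, 0.15), class = "ripsync_validation_error")
})

test_that("FIR band-pass attenuates an out-of-band tone by at least 40 dB", {
  fs <- 200
  t <- seq(0, 300 - 1 / fs, 1 / fs)
  mixed <- ts_channel(sin(2 * pi * 0.25 * t) + sin(2 * pi * 2 * t), fs)
  out <- fir_bandpass(mixed)
  i <- seq(40 * fs, 260 * fs)
  # spectral oracle: residual amplitude of the 2 Hz line in steady state
  amp2 <- fft_component_amp(out$samples[i], fs, 2)
  expect_lt(amp2, 10^(-40 / 20))
})

test_that("decimation preserves counts, rate and in-band content", {
  fs <- 200
  t <- seq(0, 600 - 1 / fs, 1 / fs)
  ch <- ts_channel(sin(2 * pi * 0.25 * t), fs)
  dn <- downsample(ch, 40)
  expect_identical(length(dn$samples), 600L * 40L)
  expect_identical(dn$sampling_rate, 40)
  # dominant DFT bin stays at 0.25 Hz
  sp <- Mod(stats::fft(dn$samples))
  half <- seq_len(length(sp) %/% 2)[-1]
  fmax <- (which.max(sp[half])) * 40 / length(dn$samples)
  expect_equal(fmax, 0.25, tolerance = 1e-6)
  # decimated output matches the analytic resampling of the band-limited input
  oracle <- sin(2 * pi * 0.25 * seq(0, 600 - 1 / 40, 1 / 40))
  i <- 2000:22000
  expect_gt(stats::cor(dn$samples[i], oracle[i]), 0.999)
  expect_error(downsample(ch, 400), class = "ripsync_validation_error")
  expect_error(downsample(ch, 33), class = "ripsync_validation_error")
})

test_that("z-normalization gives exact zero mean / unit SD and smoothing has the closed-form gain", {
  fs <- 40
  t <- seq(0, 600 - 1 / fs, 1 / fs)
  set.seed(7)
  x <- ts_channel(sin(2 * pi * 0.25 * t) + rnorm(length(t), 0, 0.2), fs)
  z <- (x$samples - mean(x$samples)) / stats::sd(x$samples)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(stats::sd(z) - 1), 1e-9)
  expect_error(znorm_and_smooth(ts_channel(rep(3, 100), fs)),
               class = "ripsync_validation_error")
  # single spike through a W-sample moving average drops by ~1/W
  spike <- numeric(4000); spike[2000] <- 1
  sm <- moving_average(ts_channel(spike, fs), 10)
  W <- 10 * fs
  expect_equal(max(sm$samples), 1 / W, tolerance = 1e-12)
  # sinusoid gain equals the discrete moving-average (Dirichlet) closed form
  s <- moving_average(ts_channel(sin(2 * pi * 0.25 * t), fs), 10)
  gain <- abs(sin(pi * 0.25 * W / fs) / (W * sin(pi * 0.25 / fs)))
  amp <- sqrt(2 * mean(s$samples[2000:22000]^2))
  expect_equal(amp, gain, tolerance = 1e-3)
})

test_that("Butterworth EMG band-pass has the designed in/out-of-band behavior", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, 1 / fs)
  mid <- quiet_butter(butter_bandpass(ts_channel(sin(2 * pi * 100 * t), fs)))
  i <- 3000:17000
  gain_mid <- sqrt(2 * mean(mid$samples[i]^2))
  expect_gt(gain_mid, 0.99); expect_lt(gain_mid, 1.01)
  low <- quiet_butter(butter_bandpass(ts_channel(sin(2 * pi * 1 * t), fs)))
  expect_lt(sqrt(2 * mean(low$samples[i]^2)), 10^(-20 / 20))
  set.seed(8)
  off <- quiet_butter(butter_bandpass(ts_channel(rnorm(length(t)) + 5, fs)))
  expect_lt(abs(mean(off$samples)), 1e-3 * 5)
  expect_error(butter_bandpass(ts_channel(rnorm(100), fs), 100, 10),
               class = "ripsync_validation_error")
})

test_that("accelerometer preprocessing passes cycles, removes gravity, rejects vibration", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, 1 / fs)
  fr <- accel_frame(sin(2 * pi * 1 * t) + 0.98,          # 1 Hz + gravity offset
                    0.2 * sin(2 * pi * 50 * t / 2),      # 25 Hz vibration
                    rep(1, length(t)), fs)
  out <- accel_preprocess(fr)
  i <- 1000:5000
  # 1 Hz passed: Butterworth gain ~1 times the 0.2-s moving-average gain
  ma_gain <- abs(sin(pi * 1 * 0.2) / (20 * sin(pi * 1 / fs)))
  expect_gt(sqrt(2 * mean(out$acc_x[i]^2)), 0.98 * ma_gain)
  expect_lt(abs(mean(out$acc_z[i])) / 0.98, 1.5e-3)      # gravity removed
  amp_vib <- fft_component_amp(out$acc_y[i], fs, 25)
  expect_lt(amp_vib / 0.2, 10^(-30 / 20))                # >= 30 dB down
})
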