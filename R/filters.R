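#' Zero-phase FIR band-pass filter
#'
#' Window-method (Hamming) linear-phase FIR band-pass, the first stage of the
#' RIP chain. The filter order is chosen so the stopband attenuation reaches
#' at least 40 dB one octave outside the band edges; the symmetric impulse
#' response is applied by FFT convolution and the integer group delay is
#' removed, giving an exactly zero-phase filter. DC is rejected.
#'
#' @param x A [ts_channel()].
#' @param low_hz,high_hz Band edges in Hz (defaults 0.15 and 0.45, the
#'   breathing band).
#' @param n_taps Optional odd filter length; by default derived from the
#'   transition width `min(low_hz / 2, high_hz)` via the Hamming-window rule.
#' @return Filtered [ts_channel()] of the same length.
#' @export
fir_bandpass <- function(x, low_hz = 0.15, high_hz = 0.45, n_taps = NULL) {
  x <- as_ts_channel(x)
  fs <- x$sampling_rate
  if (!(low_hz > 0 && high_hz > low_hz)) {
    rlang::abort("Need 0 < low_hz < high_hz.", class = "ripsync_validation_error")
  }
  if (fs <= 2 * high_hz) {
    rlang::abort("sampling_rate must exceed twice the upper band edge.",
                 class = "ripsync_validation_error")
  }
  if (is.null(n_taps)) {
    tw <- min(low_hz / 2, high_hz)        # transition to an octave below/above
    n_taps <- ceiling(3.3 * fs / tw)      # Hamming window: ~53 dB stopband
    if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  }
  if (length(x$samples) <= n_taps) {
    rlang::abort(sprintf(
      "Signal (%d samples) shorter than the FIR filter (%d taps).",
      length(x$samples), n_taps), class = "ripsync_validation_error")
  }
  h <- signal::fir1(n_taps - 1, c(low_hz, high_hz) / (fs / 2), type = "pass")
  h <- h - mean(h)                    # exact DC null
  y <- fft_filter_zero_phase(x$samples - mean(x$samples), h)
  ts_rewrap(x, y)
}

# Linear-phase FIR applied via FFT linear convolution; the (odd-length,
# symmetric) kernel's group delay (ntaps-1)/2 is removed so the net filter is
# zero phase. Edges see implicit zero padding.
fft_filter_zero_phase <- function(x, h) {
  n <- length(x); k <- length(h)
  stopifnot(k %% 2 == 1)
  m <- stats::nextn(n + k - 1, 2)
  X <- stats::fft(c(x, rep(0, m - n)))
  H <- stats::fft(c(h, rep(0, m - k)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / m
  d <- (k - 1) / 2
  y[(d + 1):(d + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' ([signal::filtfilt()]), used for EMG (10–500 Hz) and accelerometer
#' (0.1–10 Hz) preprocessing. A high cutoff at or above Nyquist is clipped to
#' 0.99 x Nyquist with a message, since such a digital cutoff is otherwise
#' unrealizable.
#'
#' @param x A [ts_channel()].
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Filter order (default 4).
#' @return Filtered [ts_channel()] of the same length.
#' @export
butter_bandpass <- function(x, low_hz = 10, high_hz = 500, order = 4) {
  x <- as_ts_channel(x)
  fs <- x$sampling_rate
  if (!(low_hz > 0 && high_hz > low_hz)) {
    rlang::abort("Need 0 < low_hz < high_hz.", class = "ripsync_validation_error")
  }
  nyq <- fs / 2
  if (high_hz >= nyq) {
    high_hz <- 0.99 * nyq
    rlang::inform(sprintf(
      "High cutoff at/above Nyquist; clipped to %.6g Hz.", high_hz),
      class = "ripsync_clip_note")
    if (low_hz >= high_hz) {
      rlang::abort("Band collapsed after Nyquist clipping.",
                   class = "ripsync_validation_error")
    }
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  y <- signal::filtfilt(bf, x$samples)
  ts_rewrap(x, y)
}

#' Decimate a channel to a lower rate
#'
#' Anti-aliased integer-factor decimation: a low-pass FIR at 80% of the new
#' Nyquist frequency is applied zero-phase, then every q-th sample is kept.
#' The target rate must divide the sampling rate.
#'
#' @param x A [ts_channel()].
#' @param target_hz Target rate in Hz (default 40).
#' @return Decimated [ts_channel()] with `sampling_rate == target_hz`.
#' @export
downsample <- function(x, target_hz = 40) {
  x <- as_ts_channel(x)
  fs <- x$sampling_rate
  if (target_hz >= fs) {
    rlang::abort("target_hz must be below the current sampling rate.",
                 class = "ripsync_validation_error")
  }
  q <- fs / target_hz
  if (abs(q - round(q)) > 1e-9) {
    rlang::abort(sprintf(
      "target_hz (%g) must divide the sampling rate (%g); got factor %.4f.",
      target_hz, fs, q), class = "ripsync_validation_error")
  }
  q <- as.integer(round(q))
  cutoff <- 0.8 * (target_hz / 2)
  n_taps <- 20L * q + 1L
  if (length(x$samples) <= n_taps) n_taps <- 2L * (length(x$samples) %/% 4L) + 1L
  h <- signal::fir1(n_taps - 1, cutoff / (fs / 2), type = "low")
  y <- fft_filter_zero_phase(x$samples, h)
  ts_rewrap(x, y[seq(1, length(y), by = q)], sampling_rate = target_hz)
}

#' Centered moving average
#'
#' Moving average with a centered window of `window_s` seconds; edges use the
#' partial window (mean over the available samples), so length is preserved
#' and no zero-fill bias is introduced.
#'
#' @param x A [ts_channel()].
#' @param window_s Window length in seconds.
#' @return Smoothed [ts_channel()].
#' @export
moving_average <- function(x, window_s) {
  x <- as_ts_channel(x)
  w <- max(1L, round(window_s * x$sampling_rate))
  ts_rewrap(x, running_mean(x$samples, w))
}

# Centered running mean, partial windows at the edges. O(n) via cumsum.
running_mean <- function(v, w) {
  n <- length(v)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' z-normalize then smooth a channel
#'
#' Standardizes the signal to mean 0 / SD 1 and then applies a centered
#' moving average (default 10 s), the final conditioning step of the RIP
#' chain before phase extraction.
#'
#' @param x A [ts_channel()].
#' @param window_s Smoothing window in seconds (default 10).
#' @return Smoothed z-scored [ts_channel()].
#' @export
znorm_and_smooth <- function(x, window_s = 10) {
  x <- as_ts_channel(x)
  s <- stats::sd(x$samples)
  if (!is.finite(s) || s == 0) {
    rlang::abort("Cannot z-normalize a zero-variance signal.",
                 class = "ripsync_validation_error")
  }
  z <- (x$samples - mean(x$samples)) / s
  moving_average(ts_rewrap(x, z), window_s)
}
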