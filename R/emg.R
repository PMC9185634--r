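#' Sliding RMS envelope
#'
#' Centered sliding root-mean-square of a (band-passed) EMG channel:
#' `sqrt` of the centered moving average of the squared signal. Length is
#' preserved (partial windows at the edges).
#'
#' @param x A [ts_channel()].
#' @param window_ms Window length in milliseconds (default 100).
#' @return Envelope as a [ts_channel()].
#' @export
rms_envelope <- function(x, window_ms = 100) {
  x <- as_ts_channel(x)
  w <- round(window_ms / 1000 * x$sampling_rate)
  if (w < 2) {
    rlang::abort("RMS window must cover at least 2 samples.",
                 class = "ripsync_validation_error")
  }
  ts_rewrap(x, sqrt(running_mean(x$samples^2, w)))
}

#' Maximal-voluntary-contraction reference amplitude
#'
#' For each MVC repetition, the RMS-smoothed signal's maximum is located and
#' the 100-ms window centered on it is averaged; the reference value is the
#' maximum of these per-repetition values across repetitions.
#'
#' @param mvc_segments List of [ts_channel()] objects, one per MVC
#'   repetition (typically three 3–4 s efforts).
#' @param muscle Muscle name carried into the result.
#' @param window_ms Averaging window around the maximum (default 100 ms).
#' @return An object of class `mvc_reference` with fields `muscle`,
#'   `reference_value` and `trial_peaks`.
#' @export
mvc_reference <- function(mvc_segments, muscle = "muscle", window_ms = 100) {
  if (length(mvc_segments) == 0L) {
    rlang::abort("Need at least one MVC segment.",
                 class = "ripsync_validation_error")
  }
  peaks <- vapply(mvc_segments, function(seg) {
    seg <- as_ts_channel(seg)
    env <- rms_envelope(seg, window_ms)$samples
    i <- which.max(env)
    w <- round(window_ms / 1000 * seg$sampling_rate)
    half_lo <- (w - 1L) %/% 2L; half_hi <- w %/% 2L
    lo <- max(1L, i - half_lo); hi <- min(length(env), i + half_hi)
    mean(env[lo:hi])
  }, numeric(1))
  structure(list(muscle = muscle, reference_value = max(peaks),
                 trial_peaks = peaks),
            class = "mvc_reference")
}

#' @export
print.mvc_reference <- function(x, ...) {
  cat(sprintf("<mvc_reference> %s: %.4g (from %d repetition(s))\n",
              x$muscle, x$reference_value, length(x$trial_peaks)))
  invisible(x)
}

#' Normalize an EMG envelope to percent MVC
#'
#' @param envelope Envelope [ts_channel()] from [rms_envelope()].
#' @param ref An [mvc_reference()].
#' @return [ts_channel()] in percent of the MVC reference.
#' @export
normalize_to_mvc <- function(envelope, ref) {
  if (!inherits(ref, "mvc_reference") || ref$reference_value <= 0) {
    rlang::abort("MVC reference must be positive.",
                 class = "ripsync_validation_error")
  }
  envelope <- as_ts_channel(envelope)
  ts_rewrap(envelope, 100 * envelope$samples / ref$reference_value,
            unit = "%MVC")
}

#' Welch power spectral density
#'
#' Welch's modified-periodogram estimate: the signal is split into
#' Hann-windowed segments of `win_s` seconds with fractional `overlap`, a
#' periodogram is computed per segment, and the periodograms are averaged.
#'
#' @param x A [ts_channel()].
#' @param win_s Segment length in seconds (default 1).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return Tibble with columns `freq_hz` and `psd`.
#' @export
welch_psd <- function(x, win_s = 1, overlap = 0.5) {
  x <- as_ts_channel(x)
  fs <- x$sampling_rate
  v <- x$samples
  nseg <- round(win_s * fs)
  if (length(v) < 2 * nseg * (1 - overlap) + nseg * overlap) {
    rlang::abort("Segment too short for Welch estimation (need >= 2 windows).",
                 class = "ripsync_validation_error")
  }
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(v) - nseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))  # Hann
  u <- sum(win^2)
  nf <- nseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- v[s:(s + nseg - 1L)] * win
    P <- Mod(stats::fft(seg))^2 / (u * fs)
    half <- P[1:nf]
    # one-sided: double all bins except DC (and Nyquist when nseg even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nf] <- 1
    acc <- acc + half * dbl
  }
  tibble::tibble(freq_hz = (0:(nf - 1)) * fs / nseg, psd = acc / length(starts))
}

#' Median frequency of an EMG segment
#'
#' Frequency below which half the Welch-estimated power lies, with linear
#' interpolation inside the crossing bin (removing bin-quantization bias).
#'
#' @param x A [ts_channel()] (band-passed EMG).
#' @param win_s,overlap Welch parameters (see [welch_psd()]).
#' @return Median frequency in Hz.
#' @export
median_frequency <- function(x, win_s = 1, overlap = 0.5) {
  psd <- welch_psd(x, win_s, overlap)
  p <- psd$psd
  tot <- sum(p)
  if (!is.finite(tot) || tot <= 0) {
    rlang::abort("Zero-power segment: median frequency undefined.",
                 class = "ripsync_validation_error")
  }
  cum <- cumsum(p)
  half <- tot / 2
  k <- which(cum >= half)[1]
  if (k == 1L) return(psd$freq_hz[1])
  f0 <- psd$freq_hz[k - 1]; f1 <- psd$freq_hz[k]
  c0 <- cum[k - 1]; c1 <- cum[k]
  f0 + (half - c0) / (c1 - c0) * (f1 - f0)
}

#' Default EMG pipeline parameters
#'
#' @return Named list: Butterworth band and order, RMS window, Welch
#'   settings, and whether median frequency is computed on the band-passed
#'   signal (`mf_on_filtered`, default `TRUE`).
#' @export
emg_params <- function() {
  list(band = c(10, 500), order = 4L, rms_ms = 100,
       welch = list(win_s = 1, overlap = 0.5), mf_on_filtered = TRUE)
}

#' EMG fatigue features per trial and decile
#'
#' For each trial of the recording and each of its ten divisions, computes
#' the mean %MVC of the RMS envelope and the Welch median frequency of the
#' (band-passed) signal within the division span.
#'
#' @param rec A [recording()] with the muscle channel and trial annotations.
#' @param muscle `"biceps"` or `"trapezius"` (channel `emg_<muscle>`).
#' @param ref An [mvc_reference()] for the muscle; when `NULL`, it is built
#'   from the recording's `mvc` annotations for this muscle.
#' @param params Parameter list as from [emg_params()].
#' @return Tibble with columns `muscle`, `trial`, `division`,
#'   `amplitude_pct_mvc`, `median_freq_hz`.
#' @export
emg_features_by_decile <- function(rec, muscle, ref = NULL, params = emg_params()) {
  chan_name <- paste0("emg_", muscle)
  if (!chan_name %in% names(rec$channels)) {
    rlang::abort(sprintf("Recording lacks channel %s.", chan_name),
                 class = "ripsync_validation_error")
  }
  ch <- rec$channels[[chan_name]]
  filt <- butter_bandpass(ch, params$band[1], params$band[2], params$order)
  if (is.null(ref)) ref <- mvc_reference_from_recording(rec, muscle, params)
  env <- normalize_to_mvc(rms_envelope(filt, params$rms_ms), ref)
  mf_src <- if (isTRUE(params$mf_on_filtered)) filt else ch
  trials <- trial_annotations(rec)
  if (nrow(trials) == 0L) {
    rlang::abort("Recording has no trial annotations.",
                 class = "ripsync_validation_error")
  }
  purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    spans <- decile_spans(tr$start_s, tr$end_s)
    purrr::map_dfr(seq_len(nrow(spans)), function(d) {
      idx <- span_index(spans$start_s[d], spans$end_s[d], ch$sampling_rate,
                        length(ch$samples))
      seg <- ts_channel(mf_src$samples[idx], ch$sampling_rate, chan_name)
      tibble::tibble(
        muscle = muscle, trial = tr$name, division = spans$division[d],
        amplitude_pct_mvc = mean(env$samples[idx]),
        median_freq_hz = median_frequency(seg, params$welch$win_s,
                                          params$welch$overlap))
    })
  })
}

# Build the MVC reference from a recording's own mvc annotations.
mvc_reference_from_recording <- function(rec, muscle, params = emg_params()) {
  ann <- rec$annotations
  mvc <- ann[ann$kind == "mvc" & ann$name == muscle, , drop = FALSE]
  if (nrow(mvc) == 0L) {
    rlang::abort(sprintf("No MVC annotations for muscle '%s'.", muscle),
                 class = "ripsync_validation_error")
  }
  ch <- rec$channels[[paste0("emg_", muscle)]]
  filt <- butter_bandpass(ch, params$band[1], params$band[2], params$order)
  segs <- lapply(seq_len(nrow(mvc)), function(i) {
    idx <- span_index(mvc$start_s[i], mvc$end_s[i], ch$sampling_rate,
                      length(ch$samples))
    ts_channel(filt$samples[idx], ch$sampling_rate, muscle)
  })
  mvc_reference(segs, muscle, params$rms_ms)
}
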