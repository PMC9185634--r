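#' Centered rolling Pearson correlation
#'
#' Rolling product-moment correlation between two equally long series over a
#' centered window. Positions where the window falls off either edge, or
#' where either series has (numerically) zero variance within the window,
#' are returned as `NA` and are excluded from downstream decile means rather
#' than zero-filled.
#'
#' @param a,b Numeric vectors of equal length.
#' @param window_s Window length in seconds.
#' @param rate Sampling rate in Hz.
#' @return Numeric vector of correlations (with `NA` at undefined positions).
#' @export
rolling_correlation <- function(a, b, window_s, rate) {
  if (length(a) != length(b)) {
    rlang::abort("Series must have equal lengths.",
                 class = "ripsync_validation_error")
  }
  w <- round(window_s * rate)
  if (w <= 2) {
    rlang::abort("Correlation window must exceed 2 samples.",
                 class = "ripsync_validation_error")
  }
  n <- length(a)
  if (w >= n) {
    rlang::abort("Correlation window must be shorter than the series.",
                 class = "ripsync_validation_error")
  }
  # O(n) via running sums over a fixed full window
  csa  <- c(0, cumsum(a));  csb  <- c(0, cumsum(b))
  csa2 <- c(0, cumsum(a^2)); csb2 <- c(0, cumsum(b^2))
  csab <- c(0, cumsum(a * b))
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  out <- rep(NA_real_, n)
  i <- (half_lo + 1L):(n - half_hi)
  lo <- i - half_lo; hi <- i + half_hi
  sa  <- csa[hi + 1L] - csa[lo];   sb  <- csb[hi + 1L] - csb[lo]
  sa2 <- csa2[hi + 1L] - csa2[lo]; sb2 <- csb2[hi + 1L] - csb2[lo]
  sab <- csab[hi + 1L] - csab[lo]
  va <- sa2 - sa^2 / w
  vb <- sb2 - sb^2 / w
  cov <- sab - sa * sb / w
  tol <- 1e-12 * w
  ok <- va > tol * pmax(sa2, 1) & vb > tol * pmax(sb2, 1)
  r <- rep(NA_real_, length(i))
  r[ok] <- cov[ok] / sqrt(va[ok] * vb[ok])
  r <- pmin(pmax(r, -1), 1)
  out[i] <- r
  out
}

#' Default RIP pipeline parameters
#'
#' @return Named list of the RIP chain's tunables: band edges, decimation
#'   target, smoothing and correlation windows, and masked-sift settings.
#' @export
rip_params <- function() {
  list(band = c(0.15, 0.45), downsample_hz = 40, smooth_s = 10,
       corr_window_s = 10,
       mask = list(freq = "auto", amp_ratio = 2, phases = 4L, max_sifts = 10L))
}

#' RIP synchrony series for every trial of a recording
#'
#' Runs the full RIP chain on the chest and abdomen channels of each trial:
#' FIR band-pass (0.15–0.45 Hz) -> decimation to 40 Hz -> masked-sift first
#' IMF -> z-normalization with 10-s moving-average smoothing; then computes
#' the centered rolling Pearson correlation and the instantaneous phase
#' synchrony (see [phase_synchrony()]) between the two conditioned signals.
#'
#' @param rec A [recording()] with `rip_chest`, `rip_abdomen` channels and
#'   trial annotations.
#' @param params Parameter list as from [rip_params()].
#' @return A tibble of class `rip_synchrony` with columns `trial`, `time_s`,
#'   `correlation`, `phase_synchrony` (one block per trial; rolling-window
#'   edges are `NA`).
#' @export
compute_rip_synchrony <- function(rec, params = rip_params()) {
  validate_recording(rec, require = "rip")
  trials <- trial_annotations(rec)
  if (nrow(trials) == 0L) {
    rlang::abort("Recording has no trial annotations.",
                 class = "ripsync_validation_error")
  }
  out <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    sl <- slice_annotation(rec, tr)
    cond <- lapply(sl$channels[c("rip_chest", "rip_abdomen")],
                   condition_rip_channel, params = params)
    chest <- cond$rip_chest; abd <- cond$rip_abdomen
    ph_c <- discrete_hilbert(chest$samples)$phase
    ph_a <- discrete_hilbert(abd$samples)$phase
    phi <- phase_synchrony(ph_c, ph_a)
    r <- rolling_correlation(chest$samples, abd$samples,
                             params$corr_window_s, chest$sampling_rate)
    tibble::tibble(trial = tr$name, time_s = channel_time(chest),
                   correlation = r, phase_synchrony = phi)
  })
  class(out) <- c("rip_synchrony", class(out))
  out
}

condition_rip_channel <- function(ch, params) {
  ch |>
    fir_bandpass(params$band[1], params$band[2]) |>
    downsample(params$downsample_hz) |>
    masked_sift_first_imf(mask_freq_hz = params$mask$freq,
                          mask_amp_ratio = params$mask$amp_ratio,
                          n_phases = params$mask$phases,
                          max_sifts = params$mask$max_sifts) |>
    znorm_and_smooth(params$smooth_s)
}

#' Decile means of a synchrony series
#'
#' Averages `correlation` and `phase_synchrony` within the ten equal
#' divisions of each trial; `NA` positions (rolling-window edges) are
#' excluded from the means.
#'
#' @param sync A `rip_synchrony` tibble from [compute_rip_synchrony()].
#' @param n Number of divisions (default 10).
#' @return Tibble with columns `trial`, `division`, `rip_corr`, `rip_sync`.
#' @export
rip_decile_means <- function(sync, n = 10L) {
  sync |>
    dplyr::group_by(.data$trial) |>
    dplyr::mutate(division = pmin(
      floor(.data$time_s / ((max(.data$time_s) + 1e-12) / n)) + 1L, n)) |>
    dplyr::group_by(.data$trial, .data$division) |>
    dplyr::summarise(
      rip_corr = mean(.data$correlation, na.rm = TRUE),
      rip_sync = mean(.data$phase_synchrony, na.rm = TRUE),
      .groups = "drop")
}
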