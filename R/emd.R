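#' First intrinsic mode function by masked-sift EMD
#'
#' Extracts the first intrinsic mode function (IMF) of a band-limited
#' oscillatory signal by masked sifting: a masking sinusoid is added to the
#' signal before sifting and subtracted from the resulting mode, and the
#' mode is averaged over several mask phases. The mask prevents mode mixing
#' when slow components (baseline drift) share the record with the breathing
#' oscillation.
#'
#' The sift itself is the classical envelope-mean iteration: cubic-spline
#' upper/lower envelopes through the local extrema (mirrored at the record
#' ends), subtract the envelope mean, repeat until the IMF conditions hold
#' (extrema and zero-crossing counts differ by at most one and the envelope
#' mean is small) or `max_sifts` is reached.
#'
#' @param x A [ts_channel()] — in the RIP chain, the filtered and
#'   downsampled breathing signal.
#' @param mask_freq_hz Mask frequency in Hz, or `"auto"` (default) to use
#'   the dominant frequency estimated from the zero-crossing rate of the
#'   (mean-removed) signal.
#' @param mask_amp_ratio Mask amplitude as a multiple of the signal SD
#'   (default 2).
#' @param n_phases Number of equispaced mask phases averaged (default 4).
#' @param max_sifts Maximum sift iterations per mask (default 10).
#' @return The first IMF as a [ts_channel()] of the same length.
#' @export
masked_sift_first_imf <- function(x, mask_freq_hz = "auto", mask_amp_ratio = 2,
                                  n_phases = 4L, max_sifts = 10L) {
  x <- as_ts_channel(x)
  v <- x$samples
  if (n_extrema(v) < 4L) {
    rlang::abort("Signal has fewer than 4 extrema; cannot sift.",
                 class = "ripsync_validation_error")
  }
  fs <- x$sampling_rate
  if (identical(mask_freq_hz, "auto")) {
    mask_freq_hz <- dominant_freq_zcr(v, fs)
  }
  amp <- mask_amp_ratio * stats::sd(v)
  t <- (seq_along(v) - 1) / fs
  imfs <- vapply(seq_len(n_phases), function(k) {
    ph <- 2 * pi * (k - 1) / n_phases
    mask <- amp * sin(2 * pi * mask_freq_hz * t + ph)
    sift_first_imf(v + mask, max_sifts) - mask
  }, numeric(length(v)))
  ts_rewrap(x, rowMeans(imfs))
}

# Dominant frequency from the zero-crossing rate of the mean-removed signal:
# each full oscillation crosses zero twice.
dominant_freq_zcr <- function(v, fs) {
  v <- v - mean(v)
  s <- sign(v)
  s[s == 0] <- 1
  zc <- sum(abs(diff(s)) > 0)
  max(zc / 2 / (length(v) / fs), 1 / (length(v) / fs))
}

n_extrema <- function(v) {
  d <- diff(v)
  sum(diff(sign(d)) != 0)
}

# Classical sift loop for the first IMF.
sift_first_imf <- function(v, max_sifts) {
  h <- v
  for (i in seq_len(max_sifts)) {
    env <- envelope_mean(h)
    if (is.null(env)) break
    h_new <- h - env
    if (imf_like(h_new) && sqrt(mean(env^2)) <= 0.1 * sqrt(mean(h_new^2))) {
      return(h_new)
    }
    h <- h_new
  }
  h
}

# Mean of the cubic-spline upper/lower envelopes; NULL when there are too
# few extrema to interpolate. Record ends are handled by mirroring the two
# nearest extrema beyond each boundary.
envelope_mean <- function(v) {
  n <- length(v)
  idx_max <- local_extrema(v, maxima = TRUE)
  idx_min <- local_extrema(v, maxima = FALSE)
  if (length(idx_max) < 2L || length(idx_min) < 2L) return(NULL)
  up <- spline_envelope(idx_max, v, n)
  lo <- spline_envelope(idx_min, v, n)
  (up + lo) / 2
}

local_extrema <- function(v, maxima = TRUE) {
  d <- diff(v)
  s <- sign(d)
  # collapse flat runs so plateaus yield a single extremum
  nz <- which(s != 0)
  if (length(nz) < 2L) return(integer(0))
  change <- which(diff(s[nz]) != 0)
  idx <- nz[change] + 1L
  keep <- if (maxima) s[nz[change]] > 0 else s[nz[change]] < 0
  idx[keep]
}

spline_envelope <- function(idx, v, n) {
  # mirror the two outermost extrema across the record boundaries
  xk <- c(2 - rev(idx[seq_len(min(2L, length(idx)))]), idx,
          2 * n - rev(idx[(length(idx) - min(2L, length(idx)) + 1L):length(idx)]))
  yk <- c(rev(v[idx[seq_len(min(2L, length(idx)))]]), v[idx],
          rev(v[idx[(length(idx) - min(2L, length(idx)) + 1L):length(idx)]]))
  o <- order(xk)
  xk <- xk[o]; yk <- yk[o]
  dup <- duplicated(xk)
  stats::spline(xk[!dup], yk[!dup], xout = seq_len(n), method = "fmm")$y
}

# Approximate IMF acceptance: extrema vs zero crossings differ by <= 1.
imf_like <- function(v) {
  ne <- n_extrema(v)
  s <- sign(v - mean(v) * 0)  # zero reference is 0 for an IMF candidate
  s[s == 0] <- 1
  zc <- sum(abs(diff(s)) > 0)
  abs(ne - zc) <= 1L
}
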