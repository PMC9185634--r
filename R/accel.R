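#' Triaxial accelerometer frame
#'
#' Container for the wrist accelerometer's three axes. With the wearer
#' grabbing the box, x, y and z are the medio-lateral, antero-posterior and
#' superior-inferior directions respectively.
#'
#' @param acc_x,acc_y,acc_z Numeric vectors of equal length (g units or any
#'   common scale — the angle formulas are scale-invariant).
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `accel_frame`.
#' @export
accel_frame <- function(acc_x, acc_y, acc_z, sampling_rate) {
  n <- length(acc_x)
  if (length(acc_y) != n || length(acc_z) != n) {
    rlang::abort("Axes must have equal lengths.",
                 class = "ripsync_validation_error")
  }
  structure(list(acc_x = as.numeric(acc_x), acc_y = as.numeric(acc_y),
                 acc_z = as.numeric(acc_z),
                 sampling_rate = as.numeric(sampling_rate)),
            class = "accel_frame")
}

#' @export
print.accel_frame <- function(x, ...) {
  cat(sprintf("<accel_frame> %d samples @ %g Hz\n", length(x$acc_x),
              x$sampling_rate))
  invisible(x)
}

# Build an accel_frame from a recording's acc_x/y/z channels.
accel_frame_from_recording <- function(rec) {
  validate_recording(rec, require = "accel")
  accel_frame(rec$channels$acc_x$samples, rec$channels$acc_y$samples,
              rec$channels$acc_z$samples, rec$channels$acc_x$sampling_rate)
}

#' Default accelerometer pipeline parameters
#'
#' @return Named list: Butterworth band/order, smoothing window, minimum
#'   plausible cycle fraction, and the per-trial angle summary statistic.
#' @export
accel_params <- function() {
  list(band = c(0.1, 10), order = 4L, smooth_s = 0.2,
       min_cycle_frac = 0.25, angle_summary = "mad")
}

# Decimate a high-rate frame to a working rate near 125 Hz before the
# narrow orientation-band filters: a 0.1-10 Hz Butterworth designed at
# 1000 Hz has a normalized band of 2e-4 and is numerically ill-conditioned,
# while the band itself contains nothing above a few Hz.
accel_working_frame <- function(frame) {
  fs <- frame$sampling_rate
  k <- max(1, floor(fs / 125))
  if (k == 1) return(frame)
  target <- fs / k
  f <- function(v) downsample(ts_channel(v, fs), target)$samples
  accel_frame(f(frame$acc_x), f(frame$acc_y), f(frame$acc_z), target)
}

#' Preprocess an accelerometer frame
#'
#' Each axis is band-passed (4th-order zero-phase Butterworth, default
#' 0.1–10 Hz — removing the static gravity offset and high-frequency
#' vibration) and then smoothed with a centered 0.2-s moving average.
#' Frames sampled well above the band (over ~250 Hz) are first decimated
#' to a working rate near 125 Hz with an anti-aliasing low-pass, which
#' keeps the narrow-band filter design well conditioned; the returned
#' frame carries the working rate.
#'
#' @param frame An [accel_frame()].
#' @param params Parameter list as from [accel_params()].
#' @return Preprocessed [accel_frame()] (possibly at a reduced rate).
#' @export
accel_preprocess <- function(frame, params = accel_params()) {
  stopifnot(inherits(frame, "accel_frame"))
  if (frame$sampling_rate <= 20) {
    rlang::abort("Accelerometer rate must exceed 20 Hz.",
                 class = "ripsync_validation_error")
  }
  frame <- accel_working_frame(frame)
  f <- function(v) {
    ch <- ts_channel(v, frame$sampling_rate) |>
      butter_bandpass(params$band[1], params$band[2], params$order) |>
      moving_average(params$smooth_s)
    ch$samples
  }
  accel_frame(f(frame$acc_x), f(frame$acc_y), f(frame$acc_z),
              frame$sampling_rate)
}

#' Pitch angle from a triaxial frame
#'
#' `pitch = atan(-acc_x / sqrt(acc_y^2 + acc_z^2))` in degrees, range
#' (-90, 90). Samples where the denominator vanishes are returned as `NA`.
#' Pitch reflects forearm pronation/supination and arm ab-/adduction.
#'
#' @param frame An [accel_frame()].
#' @return Numeric vector of angles in degrees.
#' @export
pitch <- function(frame) {
  stopifnot(inherits(frame, "accel_frame"))
  den <- sqrt(frame$acc_y^2 + frame$acc_z^2)
  out <- atan2(-frame$acc_x, den) * 180 / pi
  out[den == 0] <- NA_real_
  out
}

#' Roll angle from a triaxial frame
#'
#' `roll = atan(acc_y / acc_z)` in degrees. `acc_z == 0` with `acc_y != 0`
#' gives the ±90° limit by the sign of `acc_y`; both zero gives `NA`. Roll
#' reflects forearm/arm flexion-extension.
#'
#' @param frame An [accel_frame()].
#' @return Numeric vector of angles in degrees.
#' @export
roll <- function(frame) {
  stopifnot(inherits(frame, "accel_frame"))
  out <- atan(frame$acc_y / frame$acc_z) * 180 / pi
  zero_z <- frame$acc_z == 0
  out[zero_z] <- 90 * sign(frame$acc_y[zero_z])
  out[zero_z & frame$acc_y == 0] <- NA_real_
  out
}

#' Segment task cycles from the antero-posterior axis
#'
#' The preprocessed y-axis is z-scored, its analytic phase computed, and
#' each phase-wrap event (+pi -> -pi transition of the normalized signal's
#' analytic phase) marks the transition maximum starting a new task cycle.
#' Implausibly short cycles (shorter than `min_cycle_frac` of the median
#' cycle length) are merged into their neighbour — an automatic stand-in
#' for manual inspection. A regularity score (1 - CV of cycle lengths)
#' flags unreliable segmentations of aperiodic signals.
#'
#' @param y A [ts_channel()]: preprocessed antero-posterior axis of one
#'   trial.
#' @param min_cycle_frac Minimum plausible cycle length as a fraction of the
#'   median (default 0.25).
#' @return An object of class `cycle_segmentation`: list with `n_cycles`,
#'   `cycle_bounds` (tibble `start_s`, `end_s`), `regularity` in [0, 1] and
#'   `reliable` (regularity >= 0.5 and >= 3 cycles).
#' @export
segment_cycles <- function(y, min_cycle_frac = 0.25) {
  y <- as_ts_channel(y)
  fs <- y$sampling_rate
  s <- stats::sd(y$samples)
  if (!is.finite(s) || s == 0) {
    rlang::warn("Flat signal: no cycles found.")
    return(structure(list(n_cycles = 0L,
                          cycle_bounds = tibble::tibble(start_s = numeric(),
                                                        end_s = numeric()),
                          regularity = 0, reliable = FALSE),
                     class = "cycle_segmentation"))
  }
  z <- (y$samples - mean(y$samples)) / s
  ph <- discrete_hilbert(z)$phase
  wraps <- which(diff(ph) < -pi) + 1L     # +pi -> -pi transitions
  if (length(wraps) >= 3L) {
    # merge implausibly short cycles into their predecessor
    repeat {
      gaps <- diff(wraps)
      med <- stats::median(gaps)
      short <- which(gaps < min_cycle_frac * med)
      if (length(short) == 0L) break
      wraps <- wraps[-(short[1] + 1L)]
      if (length(wraps) < 3L) break
    }
  }
  k <- length(wraps)
  t_end <- length(z) / fs
  bounds <- if (k == 0L) {
    tibble::tibble(start_s = numeric(), end_s = numeric())
  } else {
    starts <- (wraps - 1) / fs
    tibble::tibble(start_s = starts, end_s = c(starts[-1], t_end))
  }
  gaps <- diff(wraps) / fs
  reg <- if (length(gaps) >= 2) {
    max(0, 1 - stats::sd(gaps) / mean(gaps))
  } else 0
  structure(list(n_cycles = k, cycle_bounds = bounds, regularity = reg,
                 reliable = reg >= 0.5 && k >= 3L),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation> %d cycles, regularity %.2f (%s)\n",
              x$n_cycles, x$regularity,
              if (x$reliable) "reliable" else "unreliable"))
  invisible(x)
}

#' Gravity-retaining orientation filter
#'
#' Low-passes each axis at the upper band edge (default 10 Hz, zero-phase
#' Butterworth) and smooths with the 0.2-s moving average, keeping the
#' static gravity component. Orientation angles must be computed from a
#' gravity-retaining signal — the band-pass used for cycle segmentation
#' removes the very component that encodes tilt.
#'
#' @param frame An [accel_frame()].
#' @param params Parameter list as from [accel_params()].
#' @return Low-passed [accel_frame()].
#' @export
accel_orientation_filter <- function(frame, params = accel_params()) {
  stopifnot(inherits(frame, "accel_frame"))
  frame <- accel_working_frame(frame)
  bf <- signal::butter(params$order,
                       params$band[2] / (frame$sampling_rate / 2),
                       type = "low")
  f <- function(v) {
    ch <- ts_channel(signal::filtfilt(bf, v), frame$sampling_rate) |>
      moving_average(params$smooth_s)
    ch$samples
  }
  accel_frame(f(frame$acc_x), f(frame$acc_y), f(frame$acc_z),
              frame$sampling_rate)
}

#' Per-trial accelerometer summary
#'
#' Cycle count from the band-passed antero-posterior axis plus an amplitude
#' summary of the pitch and roll angle series computed on the
#' gravity-retaining, low-passed axes (see [accel_orientation_filter()]).
#' The default summary is the mean absolute deviation about the mean (a
#' robust oscillation-amplitude proxy); `"sd"` and `"range"` are available
#' alternatives.
#'
#' @param frame A raw [accel_frame()] sliced to one trial; both
#'   conditioning paths are applied internally.
#' @param params Parameter list as from [accel_params()].
#' @return Tibble with columns `n_cycles`, `cycles_reliable`, `pitch_deg`,
#'   `roll_deg`.
#' @export
accel_trial_summary <- function(frame, params = accel_params()) {
  stopifnot(inherits(frame, "accel_frame"))
  bp <- accel_preprocess(frame, params)
  seg <- segment_cycles(ts_channel(bp$acc_y, frame$sampling_rate, "acc_y"),
                        params$min_cycle_frac)
  ofr <- accel_orientation_filter(frame, params)
  p <- pitch(ofr); r <- roll(ofr)
  summarize_angle <- function(a) {
    a <- a[is.finite(a)]
    if (length(a) == 0) return(NA_real_)
    switch(params$angle_summary,
           mad = mean(abs(a - mean(a))),
           sd = stats::sd(a),
           range = diff(range(a)),
           rlang::abort("Unknown angle_summary.",
                        class = "ripsync_validation_error"))
  }
  tibble::tibble(n_cycles = seg$n_cycles, cycles_reliable = seg$reliable,
                 pitch_deg = summarize_angle(p), roll_deg = summarize_angle(r))
}
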