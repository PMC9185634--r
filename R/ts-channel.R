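#' Uniformly sampled time-series channel
#'
#' `ts_channel()` is the elementary carrier of every raw and processed signal
#' in the package: a numeric sample vector with a sampling rate, a label and
#' an optional physical unit. All per-sample pipeline stages (filtering,
#' decimation, sifting, envelopes) consume and return `ts_channel` objects;
#' the tabular layers convert to tibbles via [as_tibble.ts_channel()].
#'
#' @param samples Numeric vector of samples (non-empty, finite rate implied).
#' @param sampling_rate Sampling rate in Hz (positive scalar).
#' @param label Short channel label, e.g. `"rip_chest"`.
#' @param unit Free-text physical unit (default `"a.u."`).
#'
#' @return An object of class `ts_channel`.
#' @export
#' @examples
#' ch <- ts_channel(sin(2 * pi * 0.25 * seq(0, 60, by = 1 / 40)), 40, "rip_chest")
#' channel_duration(ch)
ts_channel <- function(samples, sampling_rate, label = "signal", unit = "a.u.") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    rlang::abort("`samples` must be non-empty.", class = "ripsync_validation_error")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    rlang::abort("`sampling_rate` must be a positive finite scalar (Hz).",
                 class = "ripsync_validation_error")
  }
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         label = as.character(label), unit = as.character(unit)),
    class = "ts_channel"
  )
}

#' @export
print.ts_channel <- function(x, ...) {
  cat(sprintf("<ts_channel> %s: %d samples @ %g Hz (%.3f s), unit '%s'\n",
              x$label, length(x$samples), x$sampling_rate,
              channel_duration(x), x$unit))
  invisible(x)
}

#' Channel duration in seconds
#'
#' @param x A [ts_channel()].
#' @return Duration `length(samples) / sampling_rate` in seconds.
#' @export
channel_duration <- function(x) {
  stopifnot(inherits(x, "ts_channel"))
  length(x$samples) / x$sampling_rate
}

#' Sample time stamps of a channel
#'
#' Time of sample `n` is `(n - 1) / sampling_rate`, i.e. the channel's time
#' origin is the first sample.
#'
#' @param x A [ts_channel()].
#' @return Numeric vector of times in seconds.
#' @export
channel_time <- function(x) {
  stopifnot(inherits(x, "ts_channel"))
  (seq_along(x$samples) - 1) / x$sampling_rate
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Convert a channel to a tibble
#'
#' @param x A [ts_channel()].
#' @param ... Unused.
#' @return A tibble with columns `time_s` and `value`.
#' @export
as_tibble.ts_channel <- function(x, ...) {
  tibble::tibble(time_s = channel_time(x), value = x$samples)
}

# Internal: derive a new channel from an old one, keeping metadata.
ts_rewrap <- function(template, samples, sampling_rate = template$sampling_rate,
                      label = template$label, unit = template$unit) {
  ts_channel(samples, sampling_rate, label, unit)
}

# Internal: accept either a ts_channel or a bare numeric vector + rate.
as_ts_channel <- function(x, sampling_rate = NULL, label = "signal") {
  if (inherits(x, "ts_channel")) return(x)
  if (is.null(sampling_rate)) {
    rlang::abort("A bare numeric vector needs an explicit `sampling_rate`.",
                 class = "ripsync_validation_error")
  }
  ts_channel(x, sampling_rate, label)
}
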