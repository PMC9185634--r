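#' One subject's multi-channel recording
#'
#' A `recording` bundles a subject's channel set (all sharing one time origin
#' and, on disk, one sampling rate), the trial/rest/MVC annotations that
#' delimit the protocol phases, and free-form subject metadata (age, height,
#' mass, dominant side, ...).
#'
#' Annotation intervals are half-open `[start_s, end_s)` in seconds. Trial
#' annotations must be pairwise non-overlapping and every annotation must lie
#' inside the recorded duration.
#'
#' @param subject_id Subject identifier string.
#' @param channels Named list of [ts_channel()] objects.
#' @param annotations Tibble/data frame with columns `kind`
#'   (`"trial"`, `"rest"` or `"mvc"`), `name`, `start_s`, `end_s`.
#' @param metadata Named list of subject metadata.
#'
#' @return An object of class `recording`.
#' @export
recording <- function(subject_id, channels, annotations = NULL, metadata = list()) {
  if (is.null(annotations)) {
    annotations <- tibble::tibble(kind = character(), name = character(),
                                  start_s = numeric(), end_s = numeric())
  }
  annotations <- tibble::as_tibble(annotations)
  rec <- structure(
    list(subject_id = as.character(subject_id),
         channels = channels,
         annotations = annotations,
         metadata = metadata),
    class = "recording"
  )
  validate_recording(rec)
  rec
}

#' Validate a recording's invariants
#'
#' Checks channel types, the annotation schema, annotation bounds against the
#' recorded duration, and that trial annotations do not overlap. Optionally
#' checks that the channels a given pipeline stage needs are present.
#'
#' @param rec A [recording()].
#' @param require One of `"rip"`, `"emg"`, `"accel"` (may be a vector) to
#'   additionally require that stage's channels, or `NULL`.
#' @return `rec`, invisibly. Errors with class `ripsync_validation_error`
#'   when an invariant is violated.
#' @export
validate_recording <- function(rec, require = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (length(rec$channels) == 0L) {
    rlang::abort("Recording has no channels.", class = "ripsync_validation_error")
  }
  ok <- vapply(rec$channels, inherits, logical(1), what = "ts_channel")
  if (!all(ok)) {
    rlang::abort("All channels must be `ts_channel` objects.",
                 class = "ripsync_validation_error")
  }
  ann <- rec$annotations
  need <- c("kind", "name", "start_s", "end_s")
  if (!all(need %in% names(ann))) {
    rlang::abort("Annotations need columns kind, name, start_s, end_s.",
                 class = "ripsync_format_error")
  }
  dur <- max(vapply(rec$channels, channel_duration, numeric(1)))
  if (nrow(ann) > 0) {
    bad <- ann$start_s < 0 | ann$start_s >= ann$end_s | ann$end_s > dur + 1e-9
    if (any(bad)) {
      rlang::abort(
        sprintf("Annotation(s) outside signal duration or empty: %s",
                paste(ann$name[bad], collapse = ", ")),
        class = "ripsync_validation_error")
    }
    tr <- ann[ann$kind == "trial", , drop = FALSE]
    if (nrow(tr) > 1) {
      tr <- tr[order(tr$start_s), , drop = FALSE]
      if (any(tr$start_s[-1] < tr$end_s[-nrow(tr)] - 1e-9)) {
        rlang::abort("Trial annotations overlap.",
                     class = "ripsync_validation_error")
      }
    }
  }
  if (!is.null(require)) {
    needed <- list(
      rip   = c("rip_chest", "rip_abdomen"),
      emg   = c("emg_biceps", "emg_trapezius"),
      accel = c("acc_x", "acc_y", "acc_z"))
    for (stage in require) {
      miss <- setdiff(needed[[stage]], names(rec$channels))
      if (length(miss) > 0) {
        rlang::abort(
          sprintf("Recording '%s' lacks channel(s) required for %s: %s",
                  rec$subject_id, stage, paste(miss, collapse = ", ")),
          class = "ripsync_validation_error")
      }
    }
  }
  invisible(rec)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s: %d channels, %d annotations\n",
              x$subject_id, length(x$channels), nrow(x$annotations)))
  for (ch in x$channels) print(ch)
  invisible(x)
}

#' Trial annotations of a recording
#'
#' @param rec A [recording()].
#' @return Tibble of the `kind == "trial"` annotations, ordered by start time.
#' @export
trial_annotations <- function(rec) {
  ann <- rec$annotations
  out <- ann[ann$kind == "trial", , drop = FALSE]
  out[order(out$start_s), , drop = FALSE]
}

#' Restrict a recording to one annotation
#'
#' Slices every channel to the half-open interval `[start_s, end_s)` of the
#' annotation and shifts the time origin to 0. Sample index mapping is
#' `floor(start_s * rate)` (inclusive) to `floor(end_s * rate)` (exclusive),
#' so adjacent annotations never share a sample. Annotations falling inside
#' the slice are retained with shifted times; others are dropped.
#'
#' @param rec A [recording()].
#' @param ann A one-row annotation data frame (or list) with `start_s`,
#'   `end_s`, taken from `rec$annotations`.
#' @return A [recording()] restricted to the annotation span.
#' @export
slice_annotation <- function(rec, ann) {
  stopifnot(inherits(rec, "recording"))
  start_s <- ann$start_s[[1]]
  end_s <- ann$end_s[[1]]
  channels <- lapply(rec$channels, function(ch) {
    i0 <- floor(start_s * ch$sampling_rate) + 1      # 1-based inclusive
    i1 <- floor(end_s * ch$sampling_rate)            # 1-based inclusive end
    if (i0 > length(ch$samples)) {
      rlang::abort("Annotation lies beyond the channel.",
                   class = "ripsync_validation_error")
    }
    i1 <- min(i1, length(ch$samples))
    ts_rewrap(ch, ch$samples[i0:i1])
  })
  a <- rec$annotations
  keep <- a$start_s >= start_s - 1e-9 & a$end_s <= end_s + 1e-9
  a <- a[keep, , drop = FALSE]
  a$start_s <- pmax(a$start_s - start_s, 0)
  a$end_s <- pmin(a$end_s - start_s, end_s - start_s)
  recording(rec$subject_id, channels, a, rec$metadata)
}

#' Decile spans of a trial
#'
#' Splits a trial interval into ten equal, half-open, pairwise disjoint
#' divisions whose union is exactly the trial. For a 10-minute trial each
#' division is about one minute.
#'
#' @param start_s,end_s Trial bounds in seconds.
#' @param n Number of divisions (default 10).
#' @return Tibble with columns `division`, `start_s`, `end_s`.
#' @export
decile_spans <- function(start_s, end_s, n = 10L) {
  stopifnot(end_s > start_s)
  edges <- seq(start_s, end_s, length.out = n + 1)
  tibble::tibble(division = seq_len(n), start_s = edges[-(n + 1)], end_s = edges[-1])
}

# Internal: index range of a half-open [start_s, end_s) span at a given rate.
span_index <- function(start_s, end_s, rate, n_total) {
  i0 <- floor(start_s * rate) + 1
  i1 <- min(floor(end_s * rate), n_total)
  if (i0 > i1) return(integer(0))
  i0:i1
}
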