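#' Read and write multi-channel recordings
#'
#' On disk a recording is a pair of plain-text files:
#' \describe{
#'   \item{`<stem>.csv`}{One column per channel (header row = channel labels),
#'     one row per sample, all channels at a single acquisition rate. Values
#'     are written in shortest-round-trip decimal notation so a write/read
#'     cycle is bit-exact.}
#'   \item{`<stem>.json`}{Sidecar with `subject_id`, `sampling_rate`,
#'     `units` (label -> unit), `metadata`, and `annotations` (array of
#'     objects with `kind`, `name`, `start_s`, `end_s`).}
#' }
#' No binary container is used; the format is self-contained and diffable.
#' All channels are stored at the acquisition rate (1000 Hz for the default
#' generator); downsampling is a pipeline stage, never an I/O concern.
#'
#' @param rec A [recording()] whose channels share one sampling rate.
#' @param path Path to the channel `.csv` file; the sidecar path is derived
#'   by swapping the extension for `.json`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a validated [recording()].
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  rates <- vapply(rec$channels, function(ch) ch$sampling_rate, numeric(1))
  if (length(unique(rates)) != 1L) {
    rlang::abort("All channels must share one sampling rate for file storage.",
                 class = "ripsync_format_error")
  }
  lens <- vapply(rec$channels, function(ch) length(ch$samples), integer(1))
  if (length(unique(lens)) != 1L) {
    rlang::abort("All channels must have equal length for file storage.",
                 class = "ripsync_format_error")
  }
  # %.17g guarantees a bit-exact double round-trip through decimal text
  mat <- data.table::as.data.table(lapply(rec$channels, function(ch) {
    sprintf("%.17g", ch$samples)
  }))
  data.table::setnames(mat, names(rec$channels))
  data.table::fwrite(mat, path, quote = FALSE)
  sidecar <- list(
    subject_id = rec$subject_id,
    sampling_rate = unname(rates[[1]]),
    units = lapply(rec$channels, function(ch) ch$unit),
    metadata = rec$metadata,
    annotations = rec$annotations
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Recording file not found: %s", path),
                 class = "ripsync_format_error")
  }
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) {
    rlang::abort(sprintf("Missing JSON sidecar for %s (expected %s)", path, sc_path),
                 class = "ripsync_format_error")
  }
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  dat <- data.table::fread(path, colClasses = "numeric")
  rate <- as.numeric(sc$sampling_rate)
  channels <- lapply(names(dat), function(lab) {
    unit <- if (!is.null(sc$units[[lab]])) sc$units[[lab]] else "a.u."
    ts_channel(dat[[lab]], rate, lab, unit)
  })
  names(channels) <- names(dat)
  ann <- sc$annotations
  if (is.null(ann) || (is.data.frame(ann) && nrow(ann) == 0) || length(ann) == 0) {
    ann <- NULL
  } else {
    ann <- tibble::as_tibble(ann)
  }
  recording(sc$subject_id, channels, ann, as.list(sc$metadata))
}

sidecar_path <- function(path) {
  sub("\\.[^.]*$", ".json", path)
}

#' Read every recording of a study directory
#'
#' @param dir Directory containing `*.csv` recordings with JSON sidecars.
#' @return Named list of [recording()] objects (names = subject ids).
#' @export
read_study <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "ground_truth.csv"]
  recs <- lapply(files, read_recording)
  names(recs) <- vapply(recs, function(r) r$subject_id, character(1))
  recs
}
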