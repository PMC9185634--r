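#' Default full-pipeline configuration
#'
#' Nested parameter list covering every stage, suitable for YAML round-trip
#' via [read_pipeline_config()] / [yaml::write_yaml()].
#'
#' @return Named list with blocks `stages`, `rip`, `emg`, `accel`, `seed`.
#' @export
pipeline_config <- function() {
  list(stages = c("rip", "emg", "accel"),
       rip = rip_params(), emg = emg_params(), accel = accel_params(),
       seed = 1L)
}

#' Read a pipeline configuration file
#'
#' Loads a YAML (or JSON) configuration and merges it over
#' [pipeline_config()] defaults; unknown top-level keys are rejected.
#'
#' @param path Path to a YAML/JSON config file.
#' @return Merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- pipeline_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown config key(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "ripsync_format_error")
  }
  modify_defaults(base, user)
}

modify_defaults <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- modify_defaults(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Process one recording into decile metrics
#'
#' Runs the requested stages on one recording and returns the long decile
#' table: RIP rolling correlation and phase synchrony (`rip_corr`,
#' `rip_sync`), EMG %MVC amplitude and median frequency per muscle
#' (`emg_amp_biceps`, `emg_mf_biceps`, `emg_amp_trap`, `emg_mf_trap`), and
#' per-decile pitch/roll angle summaries (`pitch_deg`, `roll_deg`). The
#' per-trial accelerometer summary (cycle counts and trial-level angles) is
#' attached as attribute `"trial_summary"`, and the full per-sample
#' synchrony series as attribute `"synchrony"`.
#'
#' @param rec A [recording()].
#' @param config Configuration list as from [pipeline_config()].
#' @return Long decile tibble (`subject_id`, `trial`, `division`, `metric`,
#'   `value`) with attribute `"trial_summary"`.
#' @export
process_recording <- function(rec, config = pipeline_config()) {
  stages <- config$stages
  out <- list()
  trials <- trial_annotations(rec)
  sync <- NULL
  if ("rip" %in% stages) {
    sync <- compute_rip_synchrony(rec, config$rip)
    dm <- rip_decile_means(sync)
    out$rip <- dm |>
      tidyr::pivot_longer(c("rip_corr", "rip_sync"),
                          names_to = "metric", values_to = "value")
  }
  if ("emg" %in% stages) {
    for (muscle in c("biceps", "trapezius")) {
      feats <- emg_features_by_decile(rec, muscle, params = config$emg)
      short <- if (muscle == "biceps") "biceps" else "trap"
      out[[paste0("emg_", muscle)]] <- feats |>
        dplyr::transmute(.data$trial, .data$division,
                         !!paste0("emg_amp_", short) := .data$amplitude_pct_mvc,
                         !!paste0("emg_mf_", short) := .data$median_freq_hz) |>
        tidyr::pivot_longer(dplyr::starts_with("emg_"),
                            names_to = "metric", values_to = "value")
    }
  }
  trial_summary <- NULL
  if ("accel" %in% stages) {
    validate_recording(rec, require = "accel")
    per_trial <- list(); per_decile <- list()
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      sl <- slice_annotation(rec, tr)
      frame <- accel_frame_from_recording(sl)
      per_trial[[i]] <- dplyr::mutate(accel_trial_summary(frame, config$accel),
                                      trial = tr$name, .before = 1)
      ofr <- accel_orientation_filter(frame, config$accel)
      p <- pitch(ofr); r <- roll(ofr)
      spans <- decile_spans(0, tr$end_s - tr$start_s)
      per_decile[[i]] <- purrr::map_dfr(seq_len(nrow(spans)), function(d) {
        idx <- span_index(spans$start_s[d], spans$end_s[d],
                          ofr$sampling_rate, length(p))
        amp <- function(a) { a <- a[is.finite(a)]; mean(abs(a - mean(a))) }
        tibble::tibble(trial = tr$name, division = spans$division[d],
                       pitch_deg = amp(p[idx]), roll_deg = amp(r[idx]))
      })
    }
    out$accel <- dplyr::bind_rows(per_decile) |>
      tidyr::pivot_longer(c("pitch_deg", "roll_deg"),
                          names_to = "metric", values_to = "value")
    trial_summary <- dplyr::bind_rows(per_trial)
  }
  tbl <- dplyr::bind_rows(out) |>
    dplyr::mutate(subject_id = rec$subject_id, .before = 1) |>
    dplyr::arrange(.data$metric, .data$trial, .data$division)
  attr(tbl, "trial_summary") <- if (!is.null(trial_summary)) {
    dplyr::mutate(trial_summary, subject_id = rec$subject_id, .before = 1)
  }
  attr(tbl, "synchrony") <- sync
  tbl
}

#' Process a study directory
#'
#' Applies [process_recording()] to every recording under `in_dir`, merges
#' the decile tables and per-trial accelerometer summaries, and (when
#' `out_dir` is given) writes `decile_table.csv`, `trial_summary.csv`,
#' per-subject `synchrony_<id>.csv` series and a run `manifest.json`
#' (configuration echo, package version, subject list). A subject whose
#' processing fails is skipped with a warning; the
#' run errors only when every subject fails.
#'
#' @param in_dir Directory of recordings (see [write_recording()]).
#' @param config Configuration list as from [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with `decile_table`, `trial_summary`, `failed` (subject
#'   ids), invisibly when `out_dir` is given.
#' @export
process_study <- function(in_dir, config = pipeline_config(), out_dir = NULL) {
  files <- sort(list.files(in_dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "ground_truth.csv"]
  if (length(files) == 0) {
    rlang::abort(sprintf("No recordings found in %s", in_dir),
                 class = "ripsync_format_error")
  }
  tabs <- list(); summ <- list(); failed <- character(0)
  for (f in files) {
    res <- tryCatch({
      rec <- read_recording(f)
      process_recording(rec, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rlang::warn(sprintf("[process] subject file %s failed: %s",
                          basename(f), conditionMessage(res)))
      failed <- c(failed, basename(f))
    } else {
      tabs[[f]] <- res
      if (!is.null(attr(res, "trial_summary"))) {
        summ[[f]] <- attr(res, "trial_summary")
      }
      sync <- attr(res, "synchrony")
      if (!is.null(sync) && !is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        sid <- unique(res$subject_id)[1]
        data.table::fwrite(sync[c("trial", "time_s", "correlation",
                                  "phase_synchrony")],
                           file.path(out_dir, paste0("synchrony_", sid, ".csv")))
      }
    }
  }
  if (length(tabs) == 0) {
    rlang::abort("All subjects failed to process.", class = "ripsync_run_error")
  }
  decile_table <- dplyr::bind_rows(tabs)
  trial_summary <- if (length(summ)) dplyr::bind_rows(summ) else NULL
  result <- list(decile_table = decile_table, trial_summary = trial_summary,
                 failed = failed)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    data.table::fwrite(decile_table, file.path(out_dir, "decile_table.csv"))
    if (!is.null(trial_summary)) {
      data.table::fwrite(trial_summary, file.path(out_dir, "trial_summary.csv"))
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("ripsync")),
      config = config, n_subjects = length(tabs), failed = failed,
      timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(result))
  }
  result
}

#' Analyze a decile table with the study's model battery
#'
#' Fits the two mixed-model approaches — (1) each dependent metric against
#' trial + division, (2) RIP correlation/synchrony against trial + division
#' plus EMG covariates — runs residual diagnostics for each fit, computes
#' Pearson correlations between the RIP metrics and the EMG covariates on
#' the pooled transformed decile records, and (when a per-trial
#' accelerometer summary is supplied) one-way repeated-measures ANOVAs for
#' cycle count, pitch and roll.
#'
#' @param decile_table Long decile tibble (see [process_recording()]).
#' @param trial_summary Optional per-trial accelerometer summary.
#' @return List of class `ripsync_analysis`: `models` (named list of
#'   `tdm_fit`), `diagnostics`, `correlations`, `anovas`.
#' @export
analyze_decile_table <- function(decile_table, trial_summary = NULL) {
  metrics <- unique(decile_table$metric)
  models <- list()
  rip_dep <- intersect(c("rip_corr", "rip_sync"), metrics)
  emg_amp <- intersect(c("emg_amp_biceps", "emg_amp_trap"), metrics)
  emg_mf <- intersect(c("emg_mf_biceps", "emg_mf_trap"), metrics)
  for (m in c(rip_dep, emg_amp, emg_mf)) {
    models[[m]] <- fit_trial_division_model(decile_table, m)
  }
  if (length(emg_amp) == 2) {
    for (m in rip_dep) {
      models[[paste0(m, "_vs_emg_amp")]] <-
        fit_trial_division_model(decile_table, m, covariates = emg_amp)
    }
  }
  if (length(emg_mf) == 2) {
    for (m in rip_dep) {
      models[[paste0(m, "_vs_emg_mf")]] <-
        fit_trial_division_model(decile_table, m, covariates = emg_mf)
    }
  }
  diagnostics <- purrr::map_dfr(names(models), function(nm) {
    dplyr::mutate(residual_diagnostics(models[[nm]]), model = nm, .before = 1)
  })
  correlations <- NULL
  if (length(rip_dep) > 0 && length(c(emg_amp, emg_mf)) > 0) {
    wide <- decile_table_wide(decile_table, c(rip_dep, emg_amp, emg_mf))
    for (m in c(rip_dep, emg_amp, emg_mf)) {
      wide[[m]] <- strip_attr(yeo_johnson_z(wide[[m]]))
    }
    correlations <- purrr::map_dfr(rip_dep, function(rm) {
      purrr::map_dfr(c(emg_amp, emg_mf), function(em) {
        dplyr::mutate(pearson_r(wide[[rm]], wide[[em]]),
                      rip_metric = rm, emg_metric = em, .before = 1)
      })
    })
  }
  anovas <- NULL
  if (!is.null(trial_summary)) {
    anovas <- list()
    for (m in intersect(c("n_cycles", "pitch_deg", "roll_deg"),
                        names(trial_summary))) {
      tab <- dplyr::transmute(trial_summary, .data$subject_id, .data$trial,
                              value = as.numeric(.data[[m]]))
      anovas[[m]] <- rm_anova(tab)
    }
  }
  structure(list(models = models, diagnostics = diagnostics,
                 correlations = correlations, anovas = anovas),
            class = "ripsync_analysis")
}

#' @export
print.ripsync_analysis <- function(x, ...) {
  cat(sprintf("<ripsync_analysis> %d mixed model(s), %d ANOVA(s)\n",
              length(x$models), length(x$anovas)))
  for (nm in names(x$models)) {
    cat("\n==", nm, "==\n")
    print(x$models[[nm]])
  }
  if (!is.null(x$anovas)) for (nm in names(x$anovas)) {
    cat("\n==", nm, "==\n"); print(x$anovas[[nm]])
  }
  invisible(x)
}

#' Write analysis report tables
#'
#' Serializes an analysis: one delimited table per mixed model (term, beta,
#' z, p plus a subject-variation row), the diagnostics table, correlations
#' and RM-ANOVA summaries.
#'
#' @param analysis A `ripsync_analysis` from [analyze_decile_table()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_analysis_report <- function(analysis, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (nm in names(analysis$models)) {
    fit <- analysis$models[[nm]]
    tab <- dplyr::bind_rows(
      fit$terms,
      tibble::tibble(term = "Subject Variation",
                     beta = fit$random_intercept_variance,
                     z = NA_real_, p = NA_real_))
    data.table::fwrite(tab, file.path(out_dir, paste0("model_", nm, ".csv")))
  }
  data.table::fwrite(analysis$diagnostics,
                     file.path(out_dir, "diagnostics.csv"))
  if (!is.null(analysis$correlations)) {
    data.table::fwrite(analysis$correlations,
                       file.path(out_dir, "correlations.csv"))
  }
  if (!is.null(analysis$anovas)) {
    av <- purrr::map_dfr(names(analysis$anovas), function(nm) {
      dplyr::mutate(tidy(analysis$anovas[[nm]]), metric = nm, .before = 1)
    })
    data.table::fwrite(av, file.path(out_dir, "rm_anova.csv"))
  }
  invisible(out_dir)
}
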