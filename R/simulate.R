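#' Configuration of a synthetic repetitive-work study
#'
#' Returns the generator's configuration with defaults emulating the study
#' design the analysis assumes: 22 subjects, three 10-minute trials
#' (Baseline, Fatigue 1, Fatigue 2) with 2-minute rests before and after,
#' quasi-periodic breathing near 0.25 Hz with a per-trial chest–abdomen
#' phase lag, EMG amplitude/median-frequency targets per muscle and trial,
#' and a self-paced box-transfer cycle on the wrist accelerometer.
#'
#' Default per-trial parameters encode the directions the fatigue protocol
#' is expected to produce — phase synchrony and correlation drop after the
#' Baseline trial (lag means 0.72, 0.81, 0.79 rad, i.e. synchrony about
#' 0.65, 0.61, 0.62), EMG amplitude rises (biceps 16.7/19.0/18.2 %MVC,
#' trapezius 12.7/13.5/14.2 %MVC), median frequency stays near 63 Hz
#' (biceps) and 79–81 Hz (trapezius), and pitch/roll oscillation amplitude
#' grows across trials.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    n_subjects = 22L,
    sampling_rate = 1000,
    trial_length_s = 600,
    rest_length_s = 120,
    channels = c("rip", "emg", "accel"),
    trials = c("Baseline", "Fatigue 1", "Fatigue 2"),
    breathing_hz = c(mean = 0.25, sd = 0.03),
    phase_lag_rad = c(0.72, 0.81, 0.79),     # per-trial mean chest-abdomen lag
    phase_lag_drift = c(0, 0, 0),            # within-trial linear lag drift
    phase_lag_wander_sd = 0.15,              # slow within-trial lag wander,
                                             # calibrated to a ~0.10 synchrony SD
    lag_between_sd = 0.12,
    rip_noise_sd = 0.10,                     # white sensor noise vs unit amplitude
    rip_drift_amp = 0.50,                    # out-of-band baseline drift
    emg_amp_pct_mvc = list(biceps = c(16.7, 19.0, 18.2),
                           trapezius = c(12.7, 13.5, 14.2)),
    emg_mf_hz = list(biceps = c(62.8, 63.3, 62.2),
                     trapezius = c(78.5, 80.8, 79.7)),
    emg_amp_ramp = 0,                        # relative within-trial SD ramp
    emg_mf_ramp = 0,                         # within-trial MF change (Hz)
    cycles_per_trial = 90L,
    cycle_jitter = 0.08,
    pitch_deg = c(10, 14, 15),
    roll_deg = c(8, 9, 11),
    accel_noise_sd = 0.03,
    between_subject_sd = 0.10,
    seed = 20220602L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown study_config field(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "ripsync_validation_error")
  }
  cfg[names(over)] <- over
  structure(cfg, class = "study_config")
}

# Low-pass random wander: white noise spectrally confined below cut_hz,
# scaled to the requested SD. Used for lag wander and baseline drift.
slow_wander <- function(n, fs, cut_hz, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  W[f > cut_hz] <- 0
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd_target
}

# Subject-level random effects. Consumes the active RNG stream.
draw_subject_params <- function(cfg) {
  bs <- cfg$between_subject_sd
  list(
    f0 = max(0.12, stats::rnorm(1, cfg$breathing_hz[["mean"]],
                                cfg$breathing_hz[["sd"]])),
    rip_amp = stats::rlnorm(2, 0, bs),
    lag_offset = stats::rnorm(1, 0, cfg$lag_between_sd),
    emg_amp_mult = stats::rlnorm(2, 0, bs),   # biceps, trapezius
    mf_offset = stats::rnorm(2, 0, 3 * bs / 0.1),
    cycle_offset = round(stats::rnorm(1, 0, 3 * bs / 0.1)),
    angle_mult = stats::rlnorm(1, 0, bs)
  )
}

#' Generate one trial's chest/abdomen breathing pair
#'
#' Chest = frequency-modulated breathing oscillator (fundamental plus a weak
#' second harmonic) with pink-like slow baseline drift (outside the
#' 0.15–0.45 Hz band) and white sensor noise; abdomen = the same oscillator
#' delayed by the configured time-varying phase-lag series, with its own
#' drift and noise. Amplitudes are subject-specific.
#'
#' @param cfg A [study_config()].
#' @param sp Subject parameters (internal; drawn by the study generator).
#' @param trial_idx Trial number (1–3).
#' @param duration_s Trial duration (defaults to `cfg$trial_length_s`).
#' @param lag_mean Override for the mean lag (defaults to the trial's
#'   configured value plus the subject offset).
#' @return List with `chest` and `abdomen` [ts_channel()]s and `truth`
#'   (the imposed lag series and its mean).
#' @export
gen_respiration <- function(cfg, sp = NULL, trial_idx = 1L,
                            duration_s = cfg$trial_length_s,
                            lag_mean = NULL) {
  if (is.null(sp)) sp <- draw_subject_params(cfg)
  fs <- cfg$sampling_rate
  n <- round(duration_s * fs)
  t <- (0:(n - 1)) / fs
  if (is.null(lag_mean)) {
    lag_mean <- cfg$phase_lag_rad[trial_idx] + sp$lag_offset
  }
  lag <- lag_mean +
    cfg$phase_lag_drift[trial_idx] * (t / duration_s - 0.5) +
    slow_wander(n, fs, 0.03, cfg$phase_lag_wander_sd)
  f_inst <- sp$f0 * (1 + 0.05 * sin(2 * pi * 0.01 * t) +
                       slow_wander(n, fs, 0.05, 0.03))
  phase <- cumsum(2 * pi * f_inst / fs)
  osc <- function(ph) sin(ph) + 0.15 * sin(2 * ph + 0.4)
  chest <- sp$rip_amp[1] * osc(phase) +
    slow_wander(n, fs, 0.05, cfg$rip_drift_amp) +
    stats::rnorm(n, 0, cfg$rip_noise_sd)
  abdomen <- sp$rip_amp[2] * osc(phase - lag) +
    slow_wander(n, fs, 0.05, cfg$rip_drift_amp) +
    stats::rnorm(n, 0, cfg$rip_noise_sd)
  list(chest = ts_channel(chest, fs, "rip_chest"),
       abdomen = ts_channel(abdomen, fs, "rip_abdomen"),
       truth = list(lag_mean = lag_mean, lag_series_40hz =
                      lag[seq(1, n, by = max(1L, round(fs / 40)))]))
}

# Gaussian noise spectrally shaped to a flat band [20, 2*mf - 20] Hz (median
# frequency mf by construction), raised-cosine edges, scaled to sd_target.
# The 20 Hz floor keeps the band clear of the analysis band-pass edge at
# 10 Hz, so the imposed median survives the measurement chain.
shaped_emg_noise <- function(n, fs, mf_hz, sd_target) {
  lo <- 20
  hi <- max(lo + 5, 2 * mf_hz - lo)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  edge <- 4
  mask <- rep(0, n)
  inb <- f >= lo & f <= hi
  mask[inb] <- 1
  rise <- f > lo - edge & f < lo
  mask[rise] <- 0.5 * (1 - cos(pi * (f[rise] - (lo - edge)) / edge))
  fall <- f > hi & f < hi + edge
  mask[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / edge))
  x <- Re(stats::fft(W * mask, inverse = TRUE) / n)
  x / stats::sd(x) * sd_target
}

#' Generate one subject's EMG channel and MVC bursts
#'
#' The task-phase EMG is Gaussian noise whose spectrum is flat over
#' `[10, 2 mf - 10]` Hz (so its median frequency is the configured target),
#' amplitude-modulated gently at the task-cycle rate, and scaled so that the
#' RMS envelope normalized by the generated MVC reference hits the
#' configured %MVC target. MVC bursts are three 3.5-s efforts with smooth
#' onset/offset; between bursts and during rests the channel carries
#' low-level baseline noise.
#'
#' @param cfg A [study_config()].
#' @param sp Subject parameters (internal).
#' @param muscle `"biceps"` or `"trapezius"`.
#' @param trial_idx Trial number (1–3).
#' @param duration_s Trial duration.
#' @param cycle_hz Task-cycle rate used for the amplitude modulation.
#' @return List with `task` (the trial's [ts_channel()]), `mvc_segments`
#'   (list of burst channels), `ref` (the [mvc_reference()] the scaling
#'   used) and `truth` (the imposed per-decile %MVC and MF targets).
#' @export
gen_emg <- function(cfg, sp = NULL, muscle = "biceps", trial_idx = 1L,
                    duration_s = cfg$trial_length_s, cycle_hz = 0.15) {
  if (is.null(sp)) sp <- draw_subject_params(cfg)
  fs <- cfg$sampling_rate
  mi <- match(muscle, c("biceps", "trapezius"))
  sigma_mvc <- sp$emg_amp_mult[mi]
  mvc_segments <- gen_mvc_bursts(fs, sigma_mvc,
                                 mf_hz = cfg$emg_mf_hz[[muscle]][1] + sp$mf_offset[mi])
  ref <- mvc_reference(mvc_segments, muscle)
  pct_target <- cfg$emg_amp_pct_mvc[[muscle]][trial_idx]
  mf_target <- cfg$emg_mf_hz[[muscle]][trial_idx] + sp$mf_offset[mi]
  # per-decile stationary segments with linearly interpolated targets
  spans <- decile_spans(0, duration_s)
  n <- round(duration_s * fs)
  task <- numeric(n)
  pct_d <- pct_target * (1 + cfg$emg_amp_ramp * (spans$division - 5.5) / 9)
  mf_d <- mf_target + cfg$emg_mf_ramp * (spans$division - 5.5) / 9
  for (d in seq_len(nrow(spans))) {
    idx <- span_index(spans$start_s[d], spans$end_s[d], fs, n)
    sd_d <- pct_d[d] / 100 * ref$reference_value
    seg <- shaped_emg_noise(length(idx), fs, mf_d[d], sd_d)
    tmod <- (idx - 1) / fs
    m <- 1 + 0.15 * sin(2 * pi * cycle_hz * tmod)
    m <- m / sqrt(mean(m^2))
    task[idx] <- seg * m
  }
  list(task = ts_channel(task, fs, paste0("emg_", muscle)),
       mvc_segments = mvc_segments, ref = ref,
       truth = list(pct_mvc = pct_d, mf_hz = mf_d))
}

gen_mvc_bursts <- function(fs, sigma_mvc, mf_hz = 80, n_bursts = 3L,
                           dur_s = 3.5) {
  lapply(seq_len(n_bursts), function(i) {
    n <- round(dur_s * fs)
    env <- rep(1, n)
    ramp <- round(0.4 * fs)
    env[1:ramp] <- 0.5 * (1 - cos(pi * (1:ramp) / ramp))
    env[(n - ramp + 1):n] <- rev(env[1:ramp])
    ts_channel(shaped_emg_noise(n, fs, mf_hz, sigma_mvc) * env, fs, "mvc")
  })
}

#' Generate one trial's wrist-accelerometer frame
#'
#' The orientation oscillates at the task-cycle rate with the configured
#' pitch/roll amplitudes; the axes carry the correspondingly rotated unit
#' gravity vector, a movement-acceleration component on the
#' antero-posterior axis (one oscillation per task cycle, so cycle counting
#' has a physical carrier), and white sensor noise. Cycle lengths are
#' jittered and rescaled so the trial holds exactly the requested number of
#' cycles.
#'
#' @param cfg A [study_config()].
#' @param sp Subject parameters (internal).
#' @param trial_idx Trial number (1–3).
#' @param duration_s Trial duration.
#' @param n_cycles Number of task cycles (defaults from the config and
#'   subject offset).
#' @return List with `frame` (an [accel_frame()]) and `truth` (`n_cycles`,
#'   imposed angle amplitudes, cycle bounds).
#' @export
gen_accel <- function(cfg, sp = NULL, trial_idx = 1L,
                      duration_s = cfg$trial_length_s, n_cycles = NULL) {
  if (is.null(sp)) sp <- draw_subject_params(cfg)
  fs <- cfg$sampling_rate
  n <- round(duration_s * fs)
  if (is.null(n_cycles)) {
    n_cycles <- max(3L, cfg$cycles_per_trial + sp$cycle_offset - (trial_idx - 1L))
  }
  periods <- stats::rlnorm(n_cycles, 0, cfg$cycle_jitter)
  periods <- periods / sum(periods) * duration_s
  edges <- cumsum(c(0, periods))
  t <- (0:(n - 1)) / fs
  cyc <- findInterval(t, edges, rightmost.closed = TRUE)
  cyc <- pmin(pmax(cyc, 1L), n_cycles)
  frac <- (t - edges[cyc]) / periods[cyc]
  Phi <- 2 * pi * (cyc - 1 + frac)
  p_amp <- cfg$pitch_deg[trial_idx] * sp$angle_mult
  r_amp <- cfg$roll_deg[trial_idx] * sp$angle_mult
  pitch_rad <- p_amp * pi / 180 * sin(Phi)
  roll_rad <- r_amp * pi / 180 * sin(Phi + 0.7)
  move_amp <- 0.02 * (p_amp + r_amp)
  acc_x <- -sin(pitch_rad) + stats::rnorm(n, 0, cfg$accel_noise_sd)
  acc_y <- cos(pitch_rad) * sin(roll_rad) + move_amp * cos(Phi) +
    stats::rnorm(n, 0, cfg$accel_noise_sd)
  acc_z <- cos(pitch_rad) * cos(roll_rad) + stats::rnorm(n, 0, cfg$accel_noise_sd)
  list(frame = accel_frame(acc_x, acc_y, acc_z, fs),
       truth = list(n_cycles = n_cycles, pitch_amp_deg = p_amp,
                    roll_amp_deg = r_amp,
                    cycle_bounds = tibble::tibble(start_s = edges[-length(edges)],
                                                  end_s = edges[-1])))
}

#' Generate one subject's full recording
#'
#' Assembles the protocol timeline — MVC block (three bursts per analyzed
#' muscle), 2-minute pre-rest, the three trials back to back, 2-minute
#' post-rest — into a single multi-channel [recording()] at the acquisition
#' rate, with trial/rest/MVC annotations, plus the ground truth of every
#' imposed parameter.
#'
#' @param cfg A [study_config()].
#' @param subject_id Subject identifier.
#' @return List with `recording` and `truth`.
#' @export
gen_recording <- function(cfg, subject_id = "S01") {
  sp <- draw_subject_params(cfg)
  fs <- cfg$sampling_rate
  stages <- cfg$channels
  n_trials <- length(cfg$trials)
  mvc_block_s <- if ("emg" %in% stages) 60 else 0
  total_s <- mvc_block_s + 2 * cfg$rest_length_s + n_trials * cfg$trial_length_s
  n_total <- round(total_s * fs)
  trial_starts <- mvc_block_s + cfg$rest_length_s +
    (seq_len(n_trials) - 1) * cfg$trial_length_s
  ann <- tibble::tibble(
    kind = c("rest", rep("trial", n_trials), "rest"),
    name = c("rest_pre", cfg$trials, "rest_post"),
    start_s = c(mvc_block_s, trial_starts,
                trial_starts[n_trials] + cfg$trial_length_s),
    end_s = c(mvc_block_s + cfg$rest_length_s,
              trial_starts + cfg$trial_length_s,
              trial_starts[n_trials] + cfg$trial_length_s + cfg$rest_length_s))
  if (cfg$rest_length_s <= 0) ann <- ann[ann$kind != "rest", , drop = FALSE]
  channels <- list()
  truth <- list(subject_id = subject_id, f0 = sp$f0)

  if ("rip" %in% stages) {
    # build the trace segment-wise: quiet breathing (small lag) outside the
    # trials, the configured lag profile within each trial
    pre_s <- mvc_block_s + cfg$rest_length_s
    lag_means <- numeric(n_trials)
    segs_c <- list(); segs_a <- list(); si <- 1L
    if (pre_s > 0) {
      q <- gen_respiration(cfg, sp, 1L, duration_s = pre_s, lag_mean = 0.2)
      segs_c[[si]] <- q$chest$samples; segs_a[[si]] <- q$abdomen$samples
      si <- si + 1L
    }
    for (k in seq_len(n_trials)) {
      g <- gen_respiration(cfg, sp, k)
      segs_c[[si]] <- g$chest$samples; segs_a[[si]] <- g$abdomen$samples
      lag_means[k] <- g$truth$lag_mean
      si <- si + 1L
    }
    if (cfg$rest_length_s > 0) {
      q <- gen_respiration(cfg, sp, 1L, duration_s = cfg$rest_length_s,
                           lag_mean = 0.2)
      segs_c[[si]] <- q$chest$samples; segs_a[[si]] <- q$abdomen$samples
    }
    fit_len <- function(v) {
      if (length(v) < n_total) v <- c(v, rep(v[length(v)], n_total - length(v)))
      v[seq_len(n_total)]
    }
    chest <- fit_len(unlist(segs_c, use.names = FALSE))
    abd <- fit_len(unlist(segs_a, use.names = FALSE))
    channels$rip_chest <- ts_channel(chest, fs, "rip_chest")
    channels$rip_abdomen <- ts_channel(abd, fs, "rip_abdomen")
    truth$lag_mean <- stats::setNames(lag_means, cfg$trials)
  }

  if ("emg" %in% stages) {
    emg_truth <- list()
    for (muscle in c("biceps", "trapezius")) {
      mi <- match(muscle, c("biceps", "trapezius"))
      sigma_mvc <- sp$emg_amp_mult[mi]
      v <- stats::rnorm(n_total, 0, 0.05 * sigma_mvc)   # baseline tone
      mvc0 <- if (muscle == "biceps") 2 else 32         # burst start offsets
      bursts <- gen_mvc_bursts(fs, sigma_mvc,
                               mf_hz = cfg$emg_mf_hz[[muscle]][1] + sp$mf_offset[mi])
      mvc_ann <- tibble::tibble(kind = "mvc", name = muscle,
                                start_s = mvc0 + (0:2) * 9,
                                end_s = mvc0 + (0:2) * 9 + 3.5)
      for (b in seq_along(bursts)) {
        idx <- span_index(mvc_ann$start_s[b], mvc_ann$end_s[b], fs, n_total)
        v[idx] <- bursts[[b]]$samples[seq_along(idx)]
      }
      ref <- mvc_reference(bursts, muscle)
      tr_truth <- list()
      for (k in seq_len(n_trials)) {
        g <- gen_emg(cfg, sp, muscle, k)
        # rebuild with the reference from the embedded bursts so the imposed
        # %MVC is defined against what the pipeline will actually measure
        idx <- span_index(trial_starts[k], trial_starts[k] + cfg$trial_length_s,
                          fs, n_total)
        scale <- ref$reference_value / g$ref$reference_value
        v[idx] <- g$task$samples[seq_along(idx)] * scale
        tr_truth[[cfg$trials[k]]] <- g$truth
      }
      ann <- dplyr::bind_rows(ann, mvc_ann)
      channels[[paste0("emg_", muscle)]] <- ts_channel(v, fs, paste0("emg_", muscle))
      emg_truth[[muscle]] <- tr_truth
    }
    truth$emg <- emg_truth
  }

  if ("accel" %in% stages) {
    ax <- stats::rnorm(n_total, 0, cfg$accel_noise_sd)
    ay <- stats::rnorm(n_total, 0, cfg$accel_noise_sd)
    az <- 1 + stats::rnorm(n_total, 0, cfg$accel_noise_sd)
    acc_truth <- list()
    for (k in seq_len(n_trials)) {
      g <- gen_accel(cfg, sp, k)
      idx <- span_index(trial_starts[k], trial_starts[k] + cfg$trial_length_s,
                        fs, n_total)
      ax[idx] <- g$frame$acc_x[seq_along(idx)]
      ay[idx] <- g$frame$acc_y[seq_along(idx)]
      az[idx] <- g$frame$acc_z[seq_along(idx)]
      acc_truth[[cfg$trials[k]]] <- g$truth[c("n_cycles", "pitch_amp_deg",
                                              "roll_amp_deg")]
    }
    channels$acc_x <- ts_channel(ax, fs, "acc_x", "g")
    channels$acc_y <- ts_channel(ay, fs, "acc_y", "g")
    channels$acc_z <- ts_channel(az, fs, "acc_z", "g")
    truth$accel <- acc_truth
  }

  rec <- recording(subject_id, channels, ann,
                   metadata = list(age = 27, height_m = 1.72, mass_kg = 63.4,
                                   dominant_side = "right"))
  list(recording = rec, truth = truth)
}

#' Generate a full synthetic study
#'
#' Generates `cfg$n_subjects` recordings, optionally writing each to
#' `out_dir` in the package's plain-text recording format together with a
#' machine-readable `ground_truth.json` sidecar. Everything is a pure
#' function of the configuration (including its `seed`): the same
#' configuration produces byte-identical outputs. Ground truth never leaks
#' into the recording files themselves.
#'
#' @param cfg A [study_config()].
#' @param out_dir Output directory, or `NULL` to keep recordings in memory.
#' @return Invisibly, a list with `recordings` (named list, only when
#'   `out_dir` is `NULL`), `truth` (per-subject ground truth) and `files`.
#' @export
gen_study <- function(cfg = study_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  truths <- list(); recs <- list(); files <- character(0)
  for (i in seq_along(ids)) {
    g <- gen_recording(cfg, ids[i])
    truths[[ids[i]]] <- g$truth
    if (is.null(out_dir)) {
      recs[[ids[i]]] <- g$recording
    } else {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      path <- file.path(out_dir, paste0(ids[i], ".csv"))
      write_recording(g$recording, path)
      files <- c(files, path)
    }
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(recordings = if (is.null(out_dir)) recs else NULL,
                 truth = truths, files = files))
}

#' Simulate a decile table directly from the mixed model
#'
#' Model-level companion to the signal-level generator: draws a long decile
#' table straight from the random-intercept linear model
#' `value = intercept + trial effect + division effect + subject intercept
#' + noise`. Used for calibration studies of the statistical layer (type-I
#' error, power) where re-running the signal pipeline per replicate adds
#' nothing.
#'
#' @param n_subjects Number of subjects.
#' @param trial_effects Named numeric vector of per-trial fixed effects
#'   (first element is the reference, conventionally 0).
#' @param division_effects Numeric vector of length 10 of division effects
#'   (first conventionally 0).
#' @param subject_sd Random-intercept SD.
#' @param sigma Residual SD.
#' @param metric Metric name for the table.
#' @return Long decile tibble (`subject_id`, `trial`, `division`, `metric`,
#'   `value`).
#' @export
simulate_decile_table <- function(n_subjects = 22L,
                                  trial_effects = c(Baseline = 0,
                                                    `Fatigue 1` = 0,
                                                    `Fatigue 2` = 0),
                                  division_effects = rep(0, 10),
                                  subject_sd = 0.8, sigma = 1,
                                  metric = "metric") {
  ids <- sprintf("S%02d", seq_len(n_subjects))
  u <- stats::rnorm(n_subjects, 0, subject_sd)
  grid <- tidyr::expand_grid(subject_id = ids,
                             trial = names(trial_effects),
                             division = seq_along(division_effects))
  grid$value <- u[match(grid$subject_id, ids)] +
    trial_effects[grid$trial] +
    division_effects[grid$division] +
    stats::rnorm(nrow(grid), 0, sigma)
  grid$metric <- metric
  grid[, c("subject_id", "trial", "division", "metric", "value")]
}
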