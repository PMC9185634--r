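# Shared oracles and fixture builders. All fixtures are generated in code.

# Literal O(N^2) evaluation of the odd-index discrete Hilbert kernel sum:
# H[x](n) = (2/pi) * sum over t with (n - t) odd of x(t) / (n - t).
dht_brute_force <- function(f) {
  N <- length(f)
  g <- numeric(N)
  t0 <- 0:(N - 1)
  for (k in 1:N) {
    d <- (k - 1) - t0
    odd <- (d %% 2) != 0
    g[k] <- (2 / pi) * sum(f[odd] / d[odd])
  }
  g
}

# Amplitude of the component at frequency f_hz via the DFT (steady-state
# segment assumed); used as the independent spectral oracle.
fft_component_amp <- function(x, fs, f_hz) {
  n <- length(x)
  k <- round(f_hz * n / fs)
  2 * Mod(stats::fft(x))[k + 1] / n
}

# A single-trial two-channel RIP recording driven by the study generator.
make_rip_trial_recording <- function(cfg, lag_mean = NULL, drift = NULL,
                                     subject_id = "S01") {
  if (!is.null(drift)) cfg$phase_lag_drift <- drift
  g <- gen_respiration(cfg, trial_idx = 1L, lag_mean = lag_mean)
  ann <- tibble::tibble(kind = "trial", name = "T1", start_s = 0,
                        end_s = cfg$trial_length_s)
  recording(subject_id, list(rip_chest = g$chest, rip_abdomen = g$abdomen), ann)
}

# Small RIP-only study config used by recovery-style tests.
desk_rip_config <- function(...) {
  study_config(sampling_rate = 80, trial_length_s = 200, rest_length_s = 0,
               channels = "rip", ...)
}

# Decile table from one RIP-only study replicate (generation + pipeline).
rip_study_decile_table <- function(cfg) {
  ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  dplyr::bind_rows(lapply(ids, function(id) {
    g <- gen_recording(cfg, id)
    dm <- rip_decile_means(compute_rip_synchrony(g$recording))
    dm$subject_id <- id
    dm
  })) |>
    tidyr::pivot_longer(c("rip_corr", "rip_sync"),
                        names_to = "metric", values_to = "value")
}

quiet_butter <- function(expr) {
  withCallingHandlers(expr, ripsync_clip_note = function(c) {
    invokeRestart("muffleMessage")
  })
}
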