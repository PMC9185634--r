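test_that("study generation is a pure function of the configuration", {
  cfg <- study_config(n_subjects = 2L, sampling_rate = 80, trial_length_s = 20,
                      rest_length_s = 2, channels = "rip", seed = 77L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gen_study(cfg, d1); gen_study(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the data
  cfg2 <- study_config(n_subjects = 2L, sampling_rate = 80,
                       trial_length_s = 20, rest_length_s = 2,
                       channels = "rip", seed = 78L)
  d3 <- withr::local_tempdir(); gen_study(cfg2, d3)
  expect_false(identical(readLines(file.path(d1, "S01.csv")),
                         readLines(file.path(d3, "S01.csv"))))
})

test_that("the configuration is echoed in the generated protocol layout", {
  cfg <- study_config(n_subjects = 4L, sampling_rate = 80, trial_length_s = 15,
                      rest_length_s = 3, channels = "rip", seed = 9L)
  g <- gen_study(cfg)
  expect_length(g$recordings, 4L)
  tr <- trial_annotations(g$recordings$S03)
  expect_identical(nrow(tr), 3L)
  expect_equal(tr$end_s - tr$start_s, rep(15, 3))
  expect_identical(unname(vapply(g$truth, function(x) x$subject_id,
                                 character(1))),
                   sprintf("S%02d", 1:4))
  expect_error(study_config(not_a_field = 1),
               class = "ripsync_validation_error")
})

test_that("generated breathing concentrates its oscillatory power in the RIP band", {
  set.seed(91)
  cfg <- study_config(sampling_rate = 80, trial_length_s = 120,
                      channels = "rip", rip_noise_sd = 0.05)
  g <- gen_respiration(cfg, trial_idx = 1L)
  v <- g$chest$samples
  sp <- Mod(stats::fft(v - mean(v)))^2
  f <- (seq_along(sp) - 1) * 80 / length(sp)
  half <- f > 0 & f <= 40
  inband <- f >= 0.15 & f <= 0.45
  drift <- f > 0 & f < 0.15
  # >= 90% of non-drift power lies inside the band
  p_osc <- sum(sp[half & !drift])
  expect_gt(sum(sp[inband]) / p_osc, 0.90)
})

test_that("ground truth lives only in the sidecar, never in the channel file", {
  cfg <- study_config(n_subjects = 1L, sampling_rate = 80, trial_length_s = 10,
                      rest_length_s = 2, channels = "rip", seed = 3L)
  dir <- withr::local_tempdir()
  gen_study(cfg, dir)
  header <- readLines(file.path(dir, "S01.csv"), n = 1)
  expect_identical(header, "rip_chest,rip_abdomen")
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  sidecar <- jsonlite::read_json(file.path(dir, "S01.json"))
  expect_false("lag_mean" %in% names(sidecar))
})

test_that("model-level decile simulation has the declared layout and effects", {
  set.seed(92)
  tbl <- simulate_decile_table(5, c(A = 0, B = 2, C = 0), subject_sd = 0.1,
                               sigma = 0.1, metric = "m")
  expect_identical(nrow(tbl), 150L)
  expect_identical(dplyr::n_distinct(tbl[c("subject_id", "trial", "division")]),
                   150L)
  means <- tapply(tbl$value, tbl$trial, mean)
  expect_gt(means[["B"]] - means[["A"]], 1.5)
})

test_that("generated EMG %MVC is a ratio construction against its own MVC bursts", {
  set.seed(93)
  cfg <- study_config(trial_length_s = 20, channels = "emg",
                      between_subject_sd = 0,
                      emg_amp_pct_mvc = list(biceps = c(33, 33, 33),
                                             trapezius = c(13, 13, 13)))
  g <- quiet_butter(gen_emg(cfg, muscle = "biceps", trial_idx = 1,
                            duration_s = 20))
  env <- rms_envelope(g$task)
  pct <- normalize_to_mvc(env, g$ref)
  expect_lt(abs(mean(pct$samples) - 33), 1.5)
})
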