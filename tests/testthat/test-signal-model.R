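test_that("ts_channel enforces its invariants and reports duration exactly", {
  expect_error(ts_channel(numeric(0), 100), class = "ripsync_validation_error")
  expect_error(ts_channel(1:10, 0), class = "ripsync_validation_error")
  expect_error(ts_channel(1:10, -5), class = "ripsync_validation_error")
  ch <- ts_channel(sin(1:400), 40, "rip_chest", "a.u.")
  expect_identical(channel_duration(ch), 10)
  expect_equal(channel_time(ch)[1], 0)
  tb <- as_tibble(ch)
  expect_named(tb, c("time_s", "value"))
  expect_equal(nrow(tb), 400L)
})

test_that("recording validation catches bad annotations and missing channels", {
  ch <- ts_channel(rnorm(1000), 100, "rip_chest")
  ann_bad <- tibble::tibble(kind = "trial", name = "T1", start_s = 2, end_s = 20)
  expect_error(recording("S", list(rip_chest = ch), ann_bad),
               class = "ripsync_validation_error")
  ann_overlap <- tibble::tibble(kind = "trial", name = c("T1", "T2"),
                                start_s = c(0, 3), end_s = c(5, 8))
  expect_error(recording("S", list(rip_chest = ch), ann_overlap),
               class = "ripsync_validation_error")
  rec <- recording("S", list(rip_chest = ch),
                   tibble::tibble(kind = "trial", name = "T1",
                                  start_s = 0, end_s = 5))
  expect_error(validate_recording(rec, require = "rip"),
               regexp = "rip_abdomen",
               class = "ripsync_validation_error")
})

test_that("slice_annotation is half-open, origin-shifting, and idempotent", {
  fs <- 1000
  chans <- list(a = ts_channel(seq_len(40 * fs), fs, "a"),
                b = ts_channel(rnorm(40 * fs), fs, "b"))
  ann <- tibble::tibble(kind = "trial", name = c("T1", "T2", "T3"),
                        start_s = c(2, 12, 22), end_s = c(12, 22, 32))
  rec <- recording("S", chans, ann)
  sl <- slice_annotation(rec, ann[1, ])
  # 10 s at 1000 Hz -> exactly 10,000 samples per channel
  expect_identical(length(sl$channels$a$samples), 10000L)
  expect_identical(sl$channels$a$sampling_rate, 1000)
  expect_identical(names(sl$channels), names(chans))
  # adjacent trials never share samples
  sl2 <- slice_annotation(rec, ann[2, ])
  expect_identical(sl$channels$a$samples[10000] + 1, sl2$channels$a$samples[1])
  # re-slicing with the full span is the identity
  full <- tibble::tibble(kind = "trial", name = "all", start_s = 0, end_s = 10)
  expect_identical(slice_annotation(sl, full)$channels$a$samples,
                   sl$channels$a$samples)
  # three trials concatenate to 30 s
  durs <- vapply(1:3, function(i) {
    channel_duration(slice_annotation(rec, ann[i, ])$channels$a)
  }, numeric(1))
  expect_equal(sum(durs), 30)
})

test_that("decile spans partition a trial exactly into disjoint divisions", {
  sp <- decile_spans(30, 630)
  expect_identical(nrow(sp), 10L)
  expect_equal(sp$end_s - sp$start_s, rep(60, 10))
  expect_equal(sp$start_s[-1], sp$end_s[-10])
  expect_equal(sp$start_s[1], 30)
  expect_equal(sp$end_s[10], 630)
})

test_that("recording write/read round-trips bit-exactly", {
  fs <- 250
  set.seed(101)
  chans <- list(
    rip_chest = ts_channel(rnorm(fs * 8) * pi, fs, "rip_chest"),
    rip_abdomen = ts_channel(rnorm(fs * 8) / 3, fs, "rip_abdomen"),
    acc_y = ts_channel(runif(fs * 8, -1, 1), fs, "acc_y", "g"))
  ann <- tibble::tibble(kind = c("trial", "rest"), name = c("T1", "rest_pre"),
                        start_s = c(2, 0), end_s = c(8, 2))
  rec <- recording("S07", chans, ann, metadata = list(age = 31, mass_kg = 70.5))
  path <- file.path(withr::local_tempdir(), "S07.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$subject_id, "S07")
  for (nm in names(chans)) {
    expect_identical(back$channels[[nm]]$samples, chans[[nm]]$samples)
  }
  expect_equal(as.data.frame(back$annotations), as.data.frame(ann))
  expect_equal(back$metadata$mass_kg, 70.5)
  # missing sidecar is a format error
  file.remove(sub("\\.csv$", ".json", path))
  expect_error(read_recording(path), class = "ripsync_format_error")
})

test_that("a generated study directory yields one recording per subject with trial annotations", {
  cfg <- study_config(n_subjects = 3L, sampling_rate = 80, trial_length_s = 20,
                      rest_length_s = 2, channels = "rip", seed = 5L)
  dir <- withr::local_tempdir()
  gen_study(cfg, dir)
  recs <- read_study(dir)
  expect_length(recs, 3L)
  expect_setequal(names(recs), c("S01", "S02", "S03"))
  for (r in recs) {
    expect_identical(nrow(trial_annotations(r)), 3L)
    expect_setequal(trial_annotations(r)$name,
                    c("Baseline", "Fatigue 1", "Fatigue 2"))
  }
})
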