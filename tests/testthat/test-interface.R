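test_that("trial tables round trip through CSV with validation", {
  coh <- gen_eyeblink_cohort(small_eyeblink_config(2), traces = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(coh$trials, path)
  back <- read_trial_table(path)
  expect_equal(back$cr_amplitude, coh$trials$cr_amplitude, tolerance = 1e-12)
  expect_equal(back$trace_ref, coh$trials$trace_ref)

  broken <- coh$trials
  broken$isi_s <- NULL
  expect_error(validate_trial_table(broken), "isi_s")
  dup <- coh$trials
  dup$trial_index[2] <- dup$trial_index[1]
  expect_error(validate_trial_table(dup), "duplicate")
})

test_that("dangling trace references are reported by name", {
  coh <- gen_eyeblink_cohort(small_eyeblink_config(2, n_sessions = 1))
  dir <- withr::local_tempdir()
  refs <- coh$trials$trace_ref
  for (r in refs[-1])
    write_trace_csv(coh$eyelid[[r]], file.path(dir, paste0(r, ".csv")))
  expect_error(validate_trial_table(coh$trials, trace_dir = dir), refs[1])
  write_trace_csv(coh$eyelid[[refs[1]]],
                  file.path(dir, paste0(refs[1], ".csv")))
  expect_silent(validate_trial_table(coh$trials, trace_dir = dir))
})

test_that("traces and paw tracks round trip through CSV", {
  tr <- eyelid_trace(seq(0, 1, length.out = 90), 900, trial_id = "t1")
  p <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, p)
  back <- read_trace_csv(p)
  expect_equal(back$values, tr$values, tolerance = 1e-9)
  expect_equal(back$sampling_rate, 900, tolerance = 0.5)

  trk <- gen_gait_session(trot_config(duration = 1))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_paw_tracks(trk, p2)
  trk2 <- read_paw_tracks(p2)
  expect_equal(trk2$paws$FR$x, trk$paws$FR$x, tolerance = 1e-9)
  expect_equal(trk2$context, trk$context)
  expect_equal(trk2$frame_rate, trk$frame_rate)
})

test_that("run_config validates the standard thresholds", {
  cfg <- run_config()
  expect_equal(cfg$cr_threshold, 0.1)
  expect_equal(cfg$stationary_threshold, 0.05)
  expect_error(run_config(cr_threshold = 2), "cr_threshold")
  expect_error(run_config(contact_height = 0), "contact_height")
})

test_that("simulate is deterministic and eyeblink outputs parse", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline("simulate", run_config(seed = 11), d1)
  run_pipeline("simulate", run_config(seed = 11), d2)
  expect_identical(readLines(file.path(d1, "trials.csv")),
                   readLines(file.path(d2, "trials.csv")))
  m1 <- jsonlite::read_json(file.path(d1, "run_manifest.json"))
  m2 <- jsonlite::read_json(file.path(d2, "run_manifest.json"))
  expect_identical(m1$config_hash, m2$config_hash)
  expect_identical(m1$files, m2$files)

  run_pipeline("eyeblink", run_config(seed = 11), d1)
  curves <- read.csv(file.path(d1, "learning_curves.csv"))
  expect_true(all(c("session", "pct_cr", "mean_amplitude") %in%
                    names(curves)))
  expect_true(all(curves$pct_cr >= 0 & curves$pct_cr <= 100))
  onsets <- read.csv(file.path(d1, "onsets.csv"))
  expect_equal(nrow(onsets), 4)

  run_pipeline("gait", run_config(seed = 11), d1)
  gp <- read.csv(file.path(d1, "gait_params.csv"))
  expect_true(all(gp$duty_factor >= 0 & gp$duty_factor <= 1))
  run_pipeline("splitbelt", run_config(seed = 11), d1)
  pm <- read.csv(file.path(d1, "phase_metrics.csv"))
  expect_equal(nrow(pm), 1)
})

test_that("report refuses an empty directory and writes nothing", {
  empty <- withr::local_tempdir()
  expect_error(run_pipeline("report", run_config(), empty), "nothing")
  expect_false(file.exists(file.path(empty, "report.txt")))
  expect_error(run_pipeline("frobnicate", run_config(), empty),
               "unknown subcommand")
})

test_that("frame extraction subcommand converts images to a raw trace", {
  frames_dir <- withr::local_tempdir()
  out_dir <- withr::local_tempdir()
  open_seq <- c(0.2, 0.6, 1.0)
  for (i in seq_along(open_seq)) {
    fr <- gen_eye_frame(open_seq[i], noise_sd = 0.01, seed = i)
    EBImage::writeImage(EBImage::Image(t(fr)),
                        file.path(frames_dir, sprintf("f%02d.png", i)))
  }
  run_pipeline("extract",
               list(frames_dir = frames_dir, sampling_rate = 900,
                    seed = 1L), out_dir)
  tr <- read.csv(file.path(out_dir, "eyelid_raw_trace.csv"))
  expect_equal(nrow(tr), 3)
  expect_true(all(diff(tr$raw_px) > 0))
})
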