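test_that("CR classification follows the amplitude rule and window", {
  # ramp peaking 0.4 at CS + 250 ms (ISI 300): a CR of amplitude 0.4
  tr <- make_trace(data.frame(time = c(0.30, 0.45, 0.55),
                              value = c(0, 0.4, 0)))
  r <- classify_cr(tr, cs_onset = 0.2, isi = 0.3)
  expect_true(r$is_cr)
  expect_equal(r$amplitude, 0.4, tolerance = 1e-6)

  # threshold attained exactly counts ("at least")
  tr2 <- make_trace(data.frame(time = c(0.30, 0.45, 0.55),
                               value = c(0, 0.1, 0)))
  expect_true(classify_cr(tr2, 0.2, 0.3)$is_cr)

  # early response over by CS + 100 ms is not a CR
  tr3 <- make_trace(data.frame(time = c(0.21, 0.25, 0.299, 0.30),
                               value = c(0, 0.5, 0.02, 0)))
  r3 <- classify_cr(tr3, 0.2, 0.3)
  expect_false(r3$is_cr)
  expect_lt(r3$amplitude, 0.1)

  # null trace
  r0 <- classify_cr(make_trace(data.frame(time = numeric(0),
                                          value = numeric(0))), 0.2, 0.3)
  expect_false(r0$is_cr)
  expect_equal(r0$amplitude, 0)
})

test_that("the response window is [CS+100ms, US onset) for paired trials", {
  # closure only at the US-onset sample: excluded on paired trials
  rate <- 1000
  v <- rep(0, 1000)
  v[501] <- 0.8   # t = 0.500 s = US onset for cs_onset 0.2, ISI 0.3
  tr <- eyelid_trace(v, rate)
  expect_false(classify_cr(tr, 0.2, 0.3, "paired")$is_cr)
  # but within the extended CS-only window it counts, with its peak time
  r <- classify_cr(tr, 0.2, 0.3, "cs_only")
  expect_true(r$is_cr)
  expect_equal(r$peak_time, 0.300)
  # lower bound is inclusive
  v2 <- rep(0, 1000)
  v2[301] <- 0.6   # exactly CS + 100 ms
  expect_true(classify_cr(eyelid_trace(v2, rate), 0.2, 0.3)$is_cr)
})

test_that("classification rejects short traces and supports ISI 500 ms", {
  short <- make_trace(data.frame(time = c(0.1, 0.2), value = c(0, 0)),
                      duration = 0.4)
  expect_error(classify_cr(short, 0.2, 0.3), "shorter")
  tr <- make_trace(data.frame(time = c(0.5, 0.7, 0.8), value = c(0, 0.3, 0)))
  r <- classify_cr(tr, 0.2, 0.5, "cs_only")
  expect_true(r$is_cr)
  expect_equal(r$peak_time, 0.5, tolerance = 1e-6)
})

test_that("percent CR is a simple proportion of eligible trials", {
  expect_equal(percent_cr(rep(c(TRUE, FALSE), c(30, 80))), 100 * 30 / 110)
  expect_equal(percent_cr(rep(FALSE, 10)), 0)
  expect_equal(percent_cr(rep(TRUE, 10)), 100)
  expect_error(percent_cr(logical(0)), "empty")
})

test_that("learning onset is the first session mean amplitude above 0.1", {
  expect_equal(learning_onset(c(0.02, 0.05, 0.12, 0.30)), 3L)
  expect_equal(learning_onset(c(0.5, 0.6)), 1L)
  expect_true(is.na(learning_onset(c(0.01, 0.1, 0.1))))  # strictly above
  expect_error(learning_onset(numeric(0)), "session")
})

test_that("session metrics are invariant to trial order", {
  cl <- classify_cr_trials(gen_eyeblink_cohort(small_eyeblink_config(5),
                                               traces = FALSE))
  one <- cl[cl$mouse_id == cl$mouse_id[1], ]
  lc1 <- learning_curve(one)
  shuffled <- one[sample(nrow(one)), ]
  expect_equal(learning_curve(shuffled), lc1)
})

test_that("locomotor state integrates distance and applies the 0.05 m/s rule", {
  st <- locomotor_state(rep(0.12, 601), sampling_rate = 10)
  expect_equal(st$distance, 7.2)
  expect_equal(st$mean_speed, 0.12)
  expect_false(st$is_stationary)

  zero <- locomotor_state(rep(0, 100), sampling_rate = 10)
  expect_equal(zero$distance, 0)
  expect_true(zero$is_stationary)
  expect_equal(zero$fraction_time_walking, 0)

  expect_true(locomotor_state(rep(0.04, 50),
                              sampling_rate = 10)$is_stationary)
  expect_false(locomotor_state(rep(0.06, 50),
                               sampling_rate = 10)$is_stationary)
  expect_false(locomotor_state(rep(0.05, 50),
                               sampling_rate = 10)$is_stationary)
  expect_error(locomotor_state(c(0.1, -0.1, 0.2), sampling_rate = 10),
               "egative")
})

test_that("speed-binned amplitudes recover an identity relation", {
  set.seed(3)
  sp <- runif(4000, 0, 0.2)
  trials <- data.frame(mouse_id = rep(sprintf("m%d", 1:4), each = 1000),
                       speed = sp, amplitude = sp)
  edges <- seq(0, 0.2, by = 0.05)
  sb <- speed_binned_amplitude(trials, edges)
  expect_equal(sb$summary$mean_amplitude, sb$summary$bin_center,
               tolerance = 0.01)
  expect_equal(unname(rowSums(sb$pct_by_animal)), rep(100, 4),
               tolerance = 1e-9)
  # empty bin is missing, not zero
  sb2 <- speed_binned_amplitude(trials, c(edges, 1, 2))
  expect_true(is.na(sb2$summary$mean_amplitude[6]))
  expect_error(speed_binned_amplitude(trials, c(0.1, 0.1)), "increasing")
})

test_that("single-trial modulation partitions by previous-trial US", {
  trials <- data.frame(
    mouse_id = "m1", session = 1, trial_index = 1:9,
    us_present = rep(c(TRUE, FALSE), length.out = 9))
  trials$amplitude <- ifelse(c(NA, trials$us_present[-9]), 0.3, 0.2)
  trials$amplitude[1] <- 0.25
  m <- single_trial_modulation(trials)
  expect_equal(m$mean_after_puff, 0.3)
  expect_equal(m$mean_after_no_puff, 0.2)
  expect_equal(m$mean_difference, 0.1)
  # history-independent amplitudes: near-zero difference
  set.seed(4)
  null_tr <- data.frame(mouse_id = rep(c("a", "b"), each = 200),
                        session = 1, trial_index = rep(1:200, 2),
                        us_present = sample(c(TRUE, FALSE), 400, TRUE),
                        amplitude = runif(400))
  expect_lt(abs(single_trial_modulation(null_tr)$mean_difference), 0.1)
  expect_error(single_trial_modulation(
    data.frame(mouse_id = "m1", session = 1, trial_index = 1,
               us_present = TRUE, amplitude = 0.2)), "single-trial")
})

test_that("CR timing on CS-only trials peaks near the would-be US", {
  cfg <- small_eyeblink_config(seed = 3, n_sessions = 5,
                               trials_per_session = c(paired = 20,
                                                      cs_only = 5))
  cl <- classify_cr_trials(gen_eyeblink_cohort(cfg))
  tm <- cr_timing(cl[cl$trial_type == "cs_only", ])
  expect_equal(tm$mean_peak_time, cfg$isi, tolerance = 0.05)
  # flat traces give an empty summary, not an error
  none <- cr_timing(data.frame(mouse_id = "m", is_cr = FALSE,
                               peak_time = NA_real_))
  expect_equal(nrow(none$per_animal), 0)
  expect_true(is.na(none$mean_peak_time))
})

test_that("stationary trials have smaller amplitudes when speed couples in", {
  cfg <- small_eyeblink_config(seed = 11, speed_amplitude_slope = 1.5,
                               n_sessions = 6)
  cl <- classify_cr_trials(gen_eyeblink_cohort(cfg, traces = FALSE))
  cl$speed <- cl$speed_mps
  stationary <- cl$speed < 0.05
  late <- cl$session >= 4   # after learning is underway
  expect_lt(mean(cl$amplitude[late & stationary]),
            mean(cl$amplitude[late]))
})
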