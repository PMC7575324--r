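test_that("asymmetry is fast minus slow with sign antisymmetry", {
  expect_equal(asymmetry(0.05, 0.02), 0.03)
  expect_equal(asymmetry(0.4, 0.4), 0)
  expect_equal(asymmetry(0.02, 0.05), -asymmetry(0.05, 0.02))
  expect_true(is.na(asymmetry(NA, 0.1)))
})

test_that("built-in protocols encode the printed designs", {
  p1 <- splitbelt_protocol_single()
  expect_equal(nrow(p1), 18)   # 2 tied + 8 split + 8 tied
  expect_equal(as.vector(table(p1$phase)[c("baseline", "split", "washout")]),
               c(2, 8, 8))
  split1 <- p1[p1$phase == "split", ]
  expect_equal(unique(split1$speed_slow), 0.175)
  expect_equal(unique(split1$speed_fast), 0.375)
  expect_true(all(p1$duration_s == 60))

  p2 <- splitbelt_protocol_multi()
  expect_equal(nrow(p2), 50)
  expect_equal(as.vector(table(p2$session)), rep(10, 5))
  expect_equal(sum(p2$phase == "split"), 30)  # 7 + 10 + 10 + 3
  tied2 <- p2[p2$phase != "split", ]
  expect_equal(unique(c(tied2$speed_slow, tied2$speed_fast)), 0.2)
})

test_that("protocol validation enforces ordering and speeds", {
  expect_error(splitbelt_protocol(c("split", "baseline", "washout"),
                                  0.1, 0.2), "order")
  expect_error(splitbelt_protocol(c("baseline", "split", "washout"),
                                  c(0.2, 0.3, 0.2), c(0.2, 0.2, 0.2)),
               "speed_fast > speed_slow")
  expect_error(splitbelt_protocol(character(0), 1, 1), "empty")
  expect_error(splitbelt_protocol("baseline", 0.2, 0.3), "equal belt speeds")
})

test_that("protocols round trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  p <- splitbelt_protocol_multi()
  write_protocol(p, path)
  p2 <- read_protocol(path)
  expect_equal(as.data.frame(p2), as.data.frame(p), tolerance = 1e-12)
})

test_that("the generator realizes the exponential adaptation model", {
  cfg <- splitbelt_sim_config(noise_sd = 0, learning_rate = 0.3,
                              initial_error = -0.30, seed = 1)
  s <- gen_splitbelt_series(cfg)
  expect_equal(nrow(s), 18)
  expect_equal(s$asymmetry[s$phase == "baseline"], c(0, 0))
  split_v <- s$asymmetry[s$phase == "split"]
  expect_equal(split_v[1], -0.30)
  expect_equal(split_v, -0.30 * 0.7^(0:7), tolerance = 1e-12)
  # no learning: flat split phase and no aftereffect
  flat <- gen_splitbelt_series(splitbelt_sim_config(
    noise_sd = 0, learning_rate = 0, seed = 1))
  expect_equal(unique(flat$asymmetry[flat$phase == "split"]), -0.30)
  expect_equal(flat$asymmetry[flat$phase == "washout"][1], 0)
  # determinism
  expect_identical(gen_splitbelt_series(cfg), gen_splitbelt_series(cfg))
})

test_that("phase metrics reduce a series to its three quantities", {
  proto <- splitbelt_protocol(rep(c("baseline", "split", "washout"),
                                  c(2, 8, 2)),
                              speed_slow = rep(c(0.2, 0.175, 0.2), c(2, 8, 2)),
                              speed_fast = rep(c(0.2, 0.375, 0.2), c(2, 8, 2)))
  vals <- c(0, 0, seq(-0.30, -0.05, length.out = 8), 0.22, 0.1)
  pm <- phase_metrics(adaptation_series(proto, vals))
  expect_equal(pm$initial_error, -0.30)
  expect_equal(pm$change_over_split, 0.25)
  expect_equal(pm$aftereffect, 0.22)
  # zero series
  pm0 <- phase_metrics(adaptation_series(proto, rep(0, 12)))
  expect_equal(unlist(pm0[1:3], use.names = FALSE), c(0, 0, 0))
  # caption variant: first washout trial without baseline subtraction
  vals2 <- vals; vals2[1:2] <- 0.05
  pm2 <- phase_metrics(adaptation_series(proto, vals2),
                       aftereffect_baseline = FALSE)
  expect_equal(pm2$aftereffect, 0.22)
  # missing phase errors name the phase
  short <- adaptation_series(proto, vals)[-c(11, 12), ]
  expect_error(phase_metrics(short), "washout")
})

test_that("generator metrics match the closed-form exponential", {
  cfg <- splitbelt_sim_config(noise_sd = 0, learning_rate = 0.3,
                              initial_error = -0.30, retention = 0.8)
  pm <- phase_metrics(gen_splitbelt_series(cfg))
  ex <- splitbelt_expected_metrics(cfg)
  expect_equal(pm$initial_error, ex$initial_error, tolerance = 1e-12)
  expect_equal(pm$change_over_split, -0.30 * (0.7^7 - 1), tolerance = 1e-12)
  expect_equal(pm$aftereffect, ex$aftereffect, tolerance = 1e-12)
})

test_that("percent of initial error normalizes by the group mean", {
  m <- structure(list(initial_error = -0.30, change_over_split = 0.25,
                      aftereffect = 0.22), class = "phase_metrics")
  p <- percent_of_initial_error(list(m))
  expect_equal(p$mean_pct_change_over_split, 100 * 0.25 / 0.30,
               tolerance = 1e-9)
  m2 <- m; m2$change_over_split <- 0.30
  expect_equal(percent_of_initial_error(
    list(m2))$mean_pct_change_over_split, 100)
  m3 <- m; m3$change_over_split <- 0
  expect_equal(percent_of_initial_error(
    list(m3))$mean_pct_change_over_split, 0)
  m0 <- m; m0$initial_error <- 0
  expect_error(percent_of_initial_error(list(m0)), "zero")
})

test_that("relabeling fast/slow flips signed metrics but not percentages", {
  cfg <- splitbelt_sim_config(noise_sd = 0.01, seed = 8)
  s <- gen_splitbelt_series(cfg)
  s_flip <- s; s_flip$asymmetry <- -s_flip$asymmetry
  pm <- phase_metrics(s); pm_flip <- phase_metrics(s_flip)
  expect_equal(pm_flip$initial_error, -pm$initial_error)
  expect_equal(pm_flip$aftereffect, -pm$aftereffect)
  expect_equal(percent_of_initial_error(list(pm_flip))$mean_pct_aftereffect,
               percent_of_initial_error(list(pm))$mean_pct_aftereffect,
               tolerance = 1e-9)
})

test_that("stance-speed compliance verifies split-belt walking", {
  proto <- splitbelt_protocol_single()
  cfg <- gait_sim_config(belt_speed = c(left = 0.175, right = 0.375),
                         context = "treadmill", duration = 2, noise_sd = 0,
                         frame_rate = 500)
  tracks <- lapply(1:8, function(i) gen_gait_session(cfg))
  cp <- stance_speed_compliance(tracks, proto)
  expect_true(cp$pass)
  expect_equal(cp$trials$speed_left, rep(0.175, 8), tolerance = 0.01)
  expect_equal(cp$trials$speed_right, rep(0.375, 8), tolerance = 0.01)
  # slow side walking at the fast belt speed fails
  bad_cfg <- gait_sim_config(belt_speed = c(left = 0.375, right = 0.375),
                             context = "treadmill", duration = 2,
                             noise_sd = 0, frame_rate = 500)
  bad <- lapply(1:8, function(i) gen_gait_session(bad_cfg))
  expect_false(stance_speed_compliance(bad, proto)$pass)
  # an infinite tolerance is vacuous
  expect_true(stance_speed_compliance(bad, proto, tolerance = Inf)$pass)
})

test_that("genotype-by-phase model detects and rejects group differences", {
  set.seed(21)
  mk <- function(g, n, ae_shift = 0)
    do.call(rbind, lapply(seq_len(n), function(i) data.frame(
      animal = paste0(g, i), group = g,
      phase = c("initial_error", "change_over_split", "aftereffect"),
      value = c(-0.3, 0.27, 0.2 + ae_shift) + rnorm(3, 0, 0.03))))
  fit <- genotype_phase_model(rbind(mk("wt", 8), mk("ko", 8, -0.15)))
  ct <- fit$contrasts
  expect_lt(ct$p.value[ct$phase == "aftereffect"], 0.001)
  expect_gt(ct$p.value[ct$phase == "change_over_split"], 0.05)
  # identical groups: contrast estimates exactly zero
  a <- mk("wt", 6)
  b <- a; b$group <- "ko"; b$animal <- sub("wt", "ko", b$animal)
  fit0 <- genotype_phase_model(rbind(a, b))
  expect_equal(fit0$contrasts$estimate, rep(0, 3), tolerance = 1e-10)
  expect_error(genotype_phase_model(mk("wt", 8)), ">= 2 groups")
})
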