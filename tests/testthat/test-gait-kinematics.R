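test_that("stride segmentation recovers the generated stride count", {
  trk <- gen_gait_session(trot_config())
  s <- segment_strides(trk, "FR")
  expect_gte(n_strides(s), 8)   # 3 s at 0.3 s/stride, minus boundaries
  lp <- limb_params(s, trk)
  expect_equal(lp$stride_duration_s, rep(0.3, nrow(lp)), tolerance = 1e-9)
  # alternation and strict ordering
  ev <- sort(c(s$stance_onset, s$swing_onset))
  expect_true(all(diff(ev) > 0))
})

test_that("degenerate tracks segment to zero strides or fail loudly", {
  trk <- gen_gait_session(trot_config())
  trk$paws$FR$x <- rep(5, length(trk$time))
  trk$body_x <- rep(0, length(trk$time))
  expect_equal(n_strides(segment_strides(trk, "FR")), 0)
  trk$paws$FR$x[10] <- NaN
  expect_error(segment_strides(trk, "FR"), "finite")
})

test_that("stride count is robust to noise below the prominence guard", {
  clean <- gen_gait_session(trot_config())
  noisy <- gen_gait_session(trot_config(noise_sd = 1))  # excursion 36 mm
  expect_equal(n_strides(segment_strides(noisy, "FR")),
               n_strides(segment_strides(clean, "FR")))
})

test_that("limb parameters follow their defining arithmetic", {
  # stance 0.2 s, swing 0.1 s, swing displacement 60 mm
  cfg <- trot_config(duty_factor = 2 / 3, belt_speed = 0.2)
  trk <- gen_gait_session(cfg)
  lp <- limb_params(segment_strides(trk, "FR"), trk)
  expect_equal(mean(lp$stride_duration_s), 0.3, tolerance = 1e-9)
  expect_equal(mean(lp$cadence_hz), 1 / 0.3, tolerance = 1e-6)
  expect_equal(mean(lp$duty_factor), 2 / 3, tolerance = 0.01)
  expect_equal(mean(lp$stride_length_mm), 60, tolerance = 0.5)
  expect_equal(mean(lp$swing_velocity_mps), 0.6, tolerance = 0.01)
  expect_true(all(lp$duty_factor >= 0 & lp$duty_factor <= 1))
})

test_that("treadmill stride length is belt-compensated in the ground frame", {
  cfg <- trot_config(context = "treadmill")
  trk <- gen_gait_session(cfg)
  s <- segment_strides(trk, "FR")
  ground <- limb_params(s, trk, frame = "ground")
  belt <- limb_params(s, trk, frame = "belt")
  expect_equal(mean(ground$stride_length_mm), 0.2 * 0.3 * 1000,
               tolerance = 0.5)                       # v * T
  expect_equal(mean(belt$stride_length_mm), 0, tolerance = 0.5)
})

test_that("interlimb parameters match the symmetric-gait construction", {
  trk <- gen_gait_session(trot_config())
  il <- interlimb_params(segment_all(trk), trk)
  ph <- il$stance_phase
  expect_equal(mean(ph$stance_phase[ph$paw == "FL"]), 0.5, tolerance = 1e-6)
  expect_equal(mean(ph$stance_phase[ph$paw == "HL"]), 0, tolerance = 1e-6)
  # mirror-symmetric gait: left and right step lengths equal, asymmetry 0
  sl <- il$step_length
  fr <- mean(sl$step_length_mm[sl$paw == "FR"])
  fl <- mean(sl$step_length_mm[sl$paw == "FL"])
  expect_equal(asymmetry(fr, fl), 0, tolerance = 1e-6)
  expect_equal(mean(il$base_of_support$front_mm), 20, tolerance = 1e-6)
  expect_equal(mean(il$base_of_support$hind_mm), 20, tolerance = 1e-6)
})

test_that("support categories partition the stride and match the trot", {
  cfg <- trot_config(step_height = 60)  # tall swing: contact ~ kinematic stance
  trk <- gen_gait_session(cfg)
  il <- interlimb_params(segment_all(trk), trk)
  sup <- il$supports
  sums <- rowSums(sup[, c("support_3paw", "support_2paw_diag",
                          "support_2paw_other", "support_other")])
  expect_equal(sums, rep(1, nrow(sup)), tolerance = 1e-9)
  expect_true(all(sup[, -1] >= 0 & sup[, -1] <= 1))
  # duty 0.6 trot: diagonal pairs overlap 4-paw for 2*(0.6-0.5) of the cycle
  expect_equal(mean(sup$support_2paw_diag), 0.8, tolerance = 0.05)
  expect_equal(mean(sup$support_other), 0.2, tolerance = 0.05)
  expect_equal(mean(sup$support_3paw), 0, tolerance = 0.02)
})

test_that("a missing paw leaves the other interlimb records computable", {
  trk <- gen_gait_session(trot_config())
  strides <- segment_all(trk)
  strides$HL <- NULL
  il <- interlimb_params(strides, trk)
  expect_false("HL" %in% il$step_length$paw)
  expect_false("HR" %in% il$step_length$paw)  # homolog gone
  expect_true(all(c("FR", "FL") %in% il$step_length$paw))
})

test_that("parameters are invariant to a uniform forward translation", {
  trk <- gen_gait_session(walk_config())
  trk2 <- trk
  for (p in c("FR", "FL", "HR", "HL")) trk2$paws[[p]]$x <-
    trk2$paws[[p]]$x + 500
  trk2$body_x <- trk2$body_x + 500
  lp1 <- limb_params(segment_strides(trk, "FR"), trk)
  lp2 <- limb_params(segment_strides(trk2, "FR"), trk2)
  expect_equal(lp1, lp2, tolerance = 1e-9)
  co1 <- interlimb_params(segment_all(trk), trk)$center_of_oscillation
  co2 <- interlimb_params(segment_all(trk2), trk2)$center_of_oscillation
  expect_equal(co1, co2, tolerance = 1e-9)
})

test_that("coefficient of variation follows sd/mean", {
  expect_equal(variability(rep(3, 5)), 0)
  expect_equal(variability(c(1, 3)), sd(c(1, 3)) / 2)
  expect_equal(variability(c(1, 3)), sqrt(2) / 2, tolerance = 1e-9)
  x <- rlnorm(20)
  expect_equal(variability(3.7 * x), variability(x), tolerance = 1e-12)
  expect_error(variability(c(-1, 1)), "zero-mean")
  expect_error(variability(1), ">= 2")
})

test_that("swing trajectories resample to 100 points and average cleanly", {
  trk <- gen_gait_session(trot_config())
  tj <- align_trajectories(segment_strides(trk, "FR"), trk)
  expect_length(tj, 1)
  expect_equal(dim(tj[[1]]), c(100, 3))
  expect_true(attr(tj[[1]], "n_swings") >= 8)
  # swing z rises and returns to ground
  z <- tj[[1]][, "z"]
  expect_lt(abs(z[1]), 0.5)
  expect_equal(max(z), 6, tolerance = 0.5)
  # speed bin with no swings is absent, not zero-filled
  tj2 <- align_trajectories(segment_strides(trk, "FR"), trk,
                            speed_bins = c(0, 0.1, 0.3, 0.5))
  expect_length(tj2, 1)
  expect_match(names(tj2), "0.1-0.3")
})

test_that("first-order 3-point Savitzky-Golay equals the moving average", {
  set.seed(6)
  x <- rnorm(50)
  sg <- sgolay_smooth(x, 3)
  ma <- stats::filter(x, rep(1 / 3, 3))
  interior <- 2:49
  expect_equal(sg[interior], as.numeric(ma[interior]), tolerance = 1e-12)
  # linear ramps are fixed points of a first-order filter
  ramp <- seq(0, 5, length.out = 30)
  expect_equal(sgolay_smooth(ramp, 3), ramp, tolerance = 1e-10)
})
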