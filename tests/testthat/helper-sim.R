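# Shared fixtures, built in code at test time.

# small cohort that learns within a few sessions
small_eyeblink_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    n_mice_per_group = 2, n_sessions = 4,
    trials_per_session = c(paired = 15, cs_only = 3),
    acquisition_gain = 0.05, noise_sd = 0.02, seed = seed), list(...))
  do.call(eyeblink_sim_config, args)
}

# noise-free trot on a fine time grid (stride period an exact number of
# frames, phases on the frame grid)
trot_config <- function(...) {
  args <- utils::modifyList(list(
    duration = 3, noise_sd = 0, frame_rate = 1000,
    stride_duration = 0.3, duty_factor = 0.6, belt_speed = 0.2), list(...))
  do.call(gait_sim_config, args)
}

# lateral-sequence walk: all four phases distinct, on the frame grid
walk_config <- function(...) {
  trot_config(interlimb_phases = c(FR = 0, FL = 0.5, HR = 0.75, HL = 0.25),
              ...)
}

# eyelid trace that is `base` everywhere except linearly interpolated
# through (time, value) knots
make_trace <- function(knots, rate = 1000, duration = 1, base = 0) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  v <- rep(base, length(t))
  if (nrow(knots) > 0) {
    seg <- stats::approx(knots$time, knots$value, xout = t, rule = 1)$y
    v[!is.na(seg)] <- seg[!is.na(seg)]
  }
  eyelid_trace(pmin(pmax(v, 0), 1), rate)
}

segment_all <- function(tracks)
  lapply(stats::setNames(nm = c("FR", "FL", "HR", "HL")),
         function(p) segment_strides(tracks, p))
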