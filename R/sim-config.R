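#' Configuration for the synthetic eyeblink-conditioning cohort generator
#'
#' Bundles and validates every parameter of [gen_eyeblink_cohort()]. The
#' defaults reproduce the acquisition design of the assay being modeled:
#' sessions of 100 CS-US paired trials plus 10 CS-only trials, a 300 ms
#' inter-stimulus interval (ISI) with CS and US co-terminating (50 ms US,
#' hence a 350 ms CS), randomized 5-20 s inter-trial intervals, and eyelid
#' video sampled at 900 Hz. Group activity levels default to a hypoactive
#' group walking at 0.04 m/s on average and a control-like group at
#' 0.12 m/s.
#'
#' Acquisition dynamics follow a saturating logistic: a latent learning
#' state in \[0,1\] grows on every paired trial at rate
#' `acquisition_gain * (1 + speed_weight * speed)`, so more active animals
#' accumulate learning faster. Trial CR amplitude is
#' `state * (baseline_amplitude + speed_amplitude_slope * speed) + noise`,
#' clipped to \[0,1\].
#'
#' @param n_mice_per_group Mice per group.
#' @param n_sessions Number of acquisition sessions.
#' @param trials_per_session Named counts, `c(paired = , cs_only = )`.
#' @param isi CS-to-US onset interval, seconds (0.300 or 0.500).
#' @param us_duration US (air-puff) duration, seconds.
#' @param iti_range Inter-trial interval range, seconds, `c(low, high)`.
#' @param sampling_rate Eyelid trace sampling rate, Hz.
#' @param activity_mean_per_group Named vector of per-group mean walking
#'   speeds, m/s.
#' @param activity_sd Between-mouse SD of mean walking speed, m/s.
#' @param acquisition_gain Per-paired-trial logistic growth rate of the
#'   latent learning state (dimensionless).
#' @param speed_weight Weight of trial speed in the learning-rate term,
#'   per (m/s).
#' @param baseline_amplitude Asymptotic CR amplitude at zero speed,
#'   closure units.
#' @param speed_amplitude_slope Trial-level amplitude-speed coupling,
#'   closure units per (m/s).
#' @param noise_sd Trial amplitude noise SD, closure units.
#' @param cs_onset CS onset time within each trial trace, seconds.
#' @param trace_duration Trial trace duration, seconds.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `"eyeblink_sim_config"` (a validated list).
#' @seealso [gen_eyeblink_cohort()]
#' @export
eyeblink_sim_config <- function(n_mice_per_group = 11,
                                n_sessions = 20,
                                trials_per_session = c(paired = 100, cs_only = 10),
                                isi = 0.300,
                                us_duration = 0.050,
                                iti_range = c(5, 20),
                                sampling_rate = 900,
                                activity_mean_per_group = c(low = 0.04, high = 0.12),
                                activity_sd = 0.02,
                                acquisition_gain = 2e-4,
                                speed_weight = 10,
                                baseline_amplitude = 0.4,
                                speed_amplitude_slope = 1.0,
                                noise_sd = 0.05,
                                cs_onset = 0.2,
                                trace_duration = 1.0,
                                seed = 1L) {
  n_mice_per_group <- assert_count(n_mice_per_group, "n_mice_per_group")
  n_sessions <- assert_count(n_sessions, "n_sessions")
  if (is.null(names(trials_per_session)) ||
      !all(c("paired", "cs_only") %in% names(trials_per_session)))
    stopf("`trials_per_session` must be named c(paired = , cs_only = )")
  trials_per_session <- vapply(trials_per_session[c("paired", "cs_only")],
                               assert_count, integer(1),
                               name = "trials_per_session", min = 1L)
  assert_scalar_num(isi, "isi", lower = 0, strict_lower = TRUE)
  assert_scalar_num(us_duration, "us_duration", lower = 0, strict_lower = TRUE)
  if (length(iti_range) != 2L || !is.numeric(iti_range) ||
      iti_range[1] >= iti_range[2] || any(iti_range <= 0))
    stopf("`iti_range` must be c(low, high) with 0 < low < high")
  assert_scalar_num(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  if (!is.numeric(activity_mean_per_group) || length(activity_mean_per_group) < 1L ||
      any(activity_mean_per_group < 0))
    stopf("`activity_mean_per_group` must be non-negative speeds")
  if (is.null(names(activity_mean_per_group)))
    names(activity_mean_per_group) <-
      paste0("group", seq_along(activity_mean_per_group))
  assert_scalar_num(activity_sd, "activity_sd", 0)
  assert_scalar_num(acquisition_gain, "acquisition_gain", 0)
  assert_scalar_num(speed_weight, "speed_weight", 0)
  assert_scalar_num(baseline_amplitude, "baseline_amplitude", 0)
  assert_scalar_num(speed_amplitude_slope, "speed_amplitude_slope")
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(cs_onset, "cs_onset", 0)
  assert_scalar_num(trace_duration, "trace_duration", 0, strict_lower = TRUE)
  if (trace_duration < cs_onset + isi + us_duration)
    stopf("`trace_duration` must cover cs_onset + isi + us_duration")
  structure(list(
    n_mice_per_group = n_mice_per_group, n_sessions = n_sessions,
    trials_per_session = trials_per_session, isi = isi,
    us_duration = us_duration, iti_range = as.numeric(iti_range),
    sampling_rate = sampling_rate,
    activity_mean_per_group = activity_mean_per_group,
    activity_sd = activity_sd, acquisition_gain = acquisition_gain,
    speed_weight = speed_weight, baseline_amplitude = baseline_amplitude,
    speed_amplitude_slope = speed_amplitude_slope, noise_sd = noise_sd,
    cs_onset = cs_onset, trace_duration = trace_duration,
    seed = assert_seed(seed)), class = "eyeblink_sim_config")
}

#' Configuration for the synthetic quadruped gait generator
#'
#' Parameters of [gen_gait_session()], which emulates tracked paw
#' trajectories (x forward, y lateral, z vertical, millimetres) of the four
#' paws (FR, FL, HR, HL) plus the body center, in either an overground
#' (body advances, stance paw fixed on the ground) or a treadmill frame
#' (body stationary, stance paw moves backward at belt speed).
#'
#' @param belt_speed Walking/belt speed in m/s; either a single value or
#'   `c(left = , right = )` for split-belt conditions.
#' @param stride_duration Stride period, seconds.
#' @param duty_factor Stance duration as a fraction of stride duration,
#'   in (0, 1).
#' @param interlimb_phases Named phase offsets in \[0, 1) for paws
#'   FR, FL, HR, HL (fraction of the stride cycle; FR is the reference).
#' @param step_height Peak swing height, mm.
#' @param body_width Lateral distance between left and right paws, mm.
#' @param noise_sd Additive Gaussian position noise, mm.
#' @param duration Session duration, seconds.
#' @param frame_rate Tracking frame rate, Hz.
#' @param context `"overground"` or `"treadmill"` reference frame.
#' @param seed Integer seed.
#' @return An object of class `"gait_sim_config"`.
#' @seealso [gen_gait_session()], [gait_expected_params()]
#' @export
gait_sim_config <- function(belt_speed = 0.2,
                            stride_duration = 0.3,
                            duty_factor = 0.6,
                            interlimb_phases = c(FR = 0, FL = 0.5, HR = 0.5, HL = 0),
                            step_height = 6,
                            body_width = 20,
                            noise_sd = 0,
                            duration = 5,
                            frame_rate = 400,
                            context = c("overground", "treadmill"),
                            seed = 1L) {
  context <- match.arg(context)
  if (length(belt_speed) == 1L) {
    belt_speed <- c(left = unname(belt_speed), right = unname(belt_speed))
  } else if (length(belt_speed) == 2L) {
    if (is.null(names(belt_speed))) names(belt_speed) <- c("left", "right")
    belt_speed <- belt_speed[c("left", "right")]
  } else stopf("`belt_speed` must have length 1 or 2")
  if (any(!is.finite(belt_speed)) || any(belt_speed <= 0))
    stopf("belt speeds must be positive")
  assert_scalar_num(stride_duration, "stride_duration", 0, strict_lower = TRUE)
  assert_scalar_num(duty_factor, "duty_factor")
  if (duty_factor <= 0 || duty_factor >= 1)
    stopf("`duty_factor` must be in (0, 1)")
  paws <- c("FR", "FL", "HR", "HL")
  if (!all(paws %in% names(interlimb_phases)))
    stopf("`interlimb_phases` must be named for FR, FL, HR, HL")
  interlimb_phases <- interlimb_phases[paws]
  if (any(interlimb_phases < 0 | interlimb_phases >= 1))
    stopf("phases must lie in [0, 1)")
  assert_scalar_num(step_height, "step_height", 0, strict_lower = TRUE)
  assert_scalar_num(body_width, "body_width", 0, strict_lower = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(duration, "duration", 0, strict_lower = TRUE)
  assert_scalar_num(frame_rate, "frame_rate", 0, strict_lower = TRUE)
  structure(list(
    belt_speed = belt_speed, stride_duration = stride_duration,
    duty_factor = duty_factor, interlimb_phases = interlimb_phases,
    step_height = step_height, body_width = body_width, noise_sd = noise_sd,
    duration = duration, frame_rate = frame_rate, context = context,
    seed = assert_seed(seed)), class = "gait_sim_config")
}

#' Configuration for the synthetic split-belt adaptation generator
#'
#' Parameters of [gen_splitbelt_series()]: baseline trials fluctuate around
#' zero asymmetry; at split onset the asymmetry jumps to `initial_error`
#' and decays exponentially at `learning_rate` per trial; on washout an
#' aftereffect of opposite sign, `retention` times the adapted amount,
#' decays back to zero at the same rate.
#'
#' @param protocol A [splitbelt_protocol()] data frame.
#' @param initial_error Asymmetry imposed by the first split trial
#'   (fast - slow, parameter units; negative for step length).
#' @param learning_rate Per-trial fractional decay of the error, in \[0,1\].
#' @param retention Fraction of the adapted amount expressed as an
#'   aftereffect on washout, in \[0,1\].
#' @param noise_sd Per-trial asymmetry noise SD.
#' @param seed Integer seed.
#' @return An object of class `"splitbelt_sim_config"`.
#' @export
splitbelt_sim_config <- function(protocol = splitbelt_protocol_single(),
                                 initial_error = -0.30,
                                 learning_rate = 0.3,
                                 retention = 0.8,
                                 noise_sd = 0.02,
                                 seed = 1L) {
  protocol <- validate_protocol(protocol)
  assert_scalar_num(initial_error, "initial_error")
  assert_scalar_num(learning_rate, "learning_rate", 0, 1)
  assert_scalar_num(retention, "retention", 0, 1)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  structure(list(protocol = protocol, initial_error = initial_error,
                 learning_rate = learning_rate, retention = retention,
                 noise_sd = noise_sd, seed = assert_seed(seed)),
            class = "splitbelt_sim_config")
}
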