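#' Paw-track container
#'
#' Holds tracked 3-D positions (millimetres) of the four paws and the body
#' center over time, with the recording context needed to interpret the
#' forward (x) axis: `"overground"` (ground frame; the body advances and a
#' stance paw is stationary) or `"treadmill"` (body roughly stationary; a
#' stance paw moves backward at belt speed).
#'
#' @param time Frame times, seconds (strictly increasing, regular).
#' @param paws Named list (`FR`, `FL`, `HR`, `HL`) of lists with numeric
#'   `x`, `y`, `z` vectors (mm), all of the same length as `time`.
#' @param body_x Body-center forward position, mm.
#' @param frame_rate Frames per second.
#' @param context `"overground"` or `"treadmill"`.
#' @param belt_speed Named belt/ground speeds `c(left = , right = )`, m/s.
#' @return An object of class `"paw_tracks"`.
#' @export
paw_tracks <- function(time, paws, body_x, frame_rate,
                       context = c("overground", "treadmill"),
                       belt_speed = c(left = NA_real_, right = NA_real_)) {
  context <- match.arg(context)
  paw_names <- c("FR", "FL", "HR", "HL")
  if (!all(paw_names %in% names(paws))) stopf("paws must include FR, FL, HR, HL")
  n <- length(time)
  for (p in paw_names) for (ax in c("x", "y", "z")) {
    v <- paws[[p]][[ax]]
    if (!is.numeric(v) || length(v) != n)
      stopf("paw %s axis %s must be numeric of length %d", p, ax, n)
  }
  if (length(body_x) != n) stopf("body_x length mismatch")
  assert_scalar_num(frame_rate, "frame_rate", 0, strict_lower = TRUE)
  structure(list(time = as.numeric(time), paws = paws[paw_names],
                 body_x = as.numeric(body_x), frame_rate = frame_rate,
                 context = context, belt_speed = belt_speed),
            class = "paw_tracks")
}

#' @export
print.paw_tracks <- function(x, ...) {
  cat(sprintf("<paw_tracks> %d frames @ %g Hz (%.2f s), %s frame\n",
              length(x$time), x$frame_rate,
              diff(range(x$time)), x$context))
  invisible(x)
}

paw_side <- function(paw) ifelse(substr(paw, 2, 2) == "R", "right", "left")

# anterior-posterior offset of each paw's oscillation center relative to
# the body center (mm): front paws ahead, hind paws behind
PAW_X_OFFSET <- c(FR = 15, FL = 15, HR = -15, HL = -15)
PAW_NAMES <- c("FR", "FL", "HR", "HL")

# body-relative forward position of a paw (mm) at cycle position c in
# [0,1), for stride duration T (s), duty factor d and stance speed v (m/s).
# Stance (c < d): linear backward sweep from +A to -A; swing: forward return.
paw_x_rel <- function(cyc, T, d, v_mps) {
  A <- 1000 * v_mps * d * T / 2
  ifelse(cyc < d,
         A - 1000 * v_mps * cyc * T,
         -A + 1000 * v_mps * d * T * (cyc - d) / (1 - d))
}

#' Generate a synthetic quadruped gait session
#'
#' Renders periodic paw trajectories with the configured stride duration,
#' duty factor and interlimb phase structure. During stance the paw is on
#' the ground (z = 0; stationary in the overground frame, moving backward
#' at belt speed on the treadmill); during swing it moves forward and
#' lifts to `step_height` along a half-sine. Left and right paws sit at
#' `+/- body_width / 2` laterally; front paws oscillate ahead of the body
#' center and hind paws behind it.
#'
#' @param config A [gait_sim_config()].
#' @return A [paw_tracks()] object.
#' @examples
#' trk <- gen_gait_session(gait_sim_config(duration = 3, noise_sd = 0))
#' segment_strides(trk, "FR")
#' @export
gen_gait_session <- function(config) {
  if (!inherits(config, "gait_sim_config"))
    stopf("`config` must be a gait_sim_config")
  if (config$context == "overground" &&
      config$belt_speed["left"] != config$belt_speed["right"])
    stopf("overground context requires equal left/right speeds")
  set.seed(config$seed)
  n <- round(config$duration * config$frame_rate)
  t <- (seq_len(n) - 1) / config$frame_rate
  T <- config$stride_duration
  d <- config$duty_factor
  v_body <- mean(config$belt_speed)
  body_x <- if (config$context == "overground") 1000 * v_body * t else
    rep(0, n)
  paws <- list()
  for (p in PAW_NAMES) {
    v <- config$belt_speed[[paw_side(p)]]
    phi <- config$interlimb_phases[[p]]
    cyc <- ((t / T - phi) %% 1)
    x_rel <- paw_x_rel(cyc, T, d, v) + PAW_X_OFFSET[[p]]
    z <- ifelse(cyc < d, 0,
                config$step_height * sin(pi * (cyc - d) / (1 - d)))
    y <- rep(if (paw_side(p) == "left") config$body_width / 2 else
      -config$body_width / 2, n)
    if (config$noise_sd > 0) {
      x_rel <- x_rel + rnorm(n, 0, config$noise_sd)
      y <- y + rnorm(n, 0, config$noise_sd)
      z <- z + rnorm(n, 0, config$noise_sd)
    }
    paws[[p]] <- list(x = body_x + x_rel, y = y, z = z)
  }
  paw_tracks(t, paws, body_x, config$frame_rate, config$context,
             config$belt_speed)
}

#' Closed-form gait parameters implied by a generator configuration
#'
#' Analytic per-stride parameter values of the noise-free gait produced by
#' [gen_gait_session()]; the oracle for parameter-recovery tests of the
#' stride segmentation and parameter pipeline.
#'
#' @param config A [gait_sim_config()].
#' @param reference_paw Reference paw for stance phases.
#' @return A list with per-paw `stride_duration_s`, `cadence_hz`,
#'   `duty_factor`, `stride_length_mm`, `swing_velocity_mps`,
#'   `step_length_mm`, `double_support_pct`, `center_of_oscillation_mm`,
#'   and scalar `base_of_support_mm` and per-paw `stance_phase`.
#' @export
gait_expected_params <- function(config, reference_paw = "FR") {
  T <- config$stride_duration
  d <- config$duty_factor
  phases <- config$interlimb_phases
  v <- setNames(vapply(PAW_NAMES, function(p)
    config$belt_speed[[paw_side(p)]], numeric(1)), PAW_NAMES)
  homolog <- c(FR = "FL", FL = "FR", HR = "HL", HL = "HR")
  step_len <- dbl_sup <- numeric(4)
  names(step_len) <- names(dbl_sup) <- PAW_NAMES
  for (p in PAW_NAMES) {
    q <- homolog[[p]]
    cyc_q <- (phases[[p]] - phases[[q]]) %% 1
    step_len[p] <- (paw_x_rel(0, T, d, v[[p]]) + PAW_X_OFFSET[[p]]) -
      (paw_x_rel(cyc_q, T, d, v[[q]]) + PAW_X_OFFSET[[q]])
    dbl_sup[p] <- 100 * ((phases[[q]] - phases[[p]] + d) %% 1)
  }
  list(
    stride_duration_s = setNames(rep(T, 4), PAW_NAMES),
    cadence_hz = setNames(rep(1 / T, 4), PAW_NAMES),
    duty_factor = setNames(rep(d, 4), PAW_NAMES),
    stride_length_mm = 1000 * v * T,
    swing_velocity_mps = v / (1 - d),
    step_length_mm = step_len,
    double_support_pct = dbl_sup,
    center_of_oscillation_mm = PAW_X_OFFSET,
    base_of_support_mm = config$body_width,
    stance_phase = setNames(
      (unlist(phases) - phases[[reference_paw]]) %% 1, PAW_NAMES))
}
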