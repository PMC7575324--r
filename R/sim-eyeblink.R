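#' Generate a synthetic eyeblink-conditioning cohort
#'
#' Simulates groups of head-fixed mice acquiring conditioned eyelid
#' responses (CRs) over sessions of paired CS-US and CS-only trials, with
#' the behavioral-state structure the analysis modules are designed to
#' detect: each mouse has a characteristic locomotor activity level drawn
#' from its group's distribution, the latent learning state grows faster
#' on trials walked at higher speed (saturating logistic update,
#' see [eyeblink_sim_config()]), and trial CR amplitude is coupled to
#' trial walking speed through `speed_amplitude_slope`.
#'
#' @param config An [eyeblink_sim_config()].
#' @param traces If `TRUE`, also render per-trial normalized eyelid traces
#'   (a CR ramp peaking at the expected US time and, on paired trials, an
#'   unconditioned response reaching full closure) and wheel-speed traces.
#'   Amplitude analyses only need the trial table; traces are used by the
#'   video/classification round trips.
#' @return A list of class `"eyeblink_cohort"`:
#'   `trials` (one row per trial: `mouse_id`, `group`, `session`,
#'   `trial_index`, `trial_type`, `cs_onset_s`, `isi_s`, `us_present`,
#'   `us_duration_s`, `iti_s`, `speed_mps`, `cr_amplitude`,
#'   `learning_state`, `trace_ref`, `wheel_ref`), plus `eyelid` and
#'   `wheel` trace lists when `traces = TRUE`, and `config`.
#' @export
gen_eyeblink_cohort <- function(config, traces = TRUE) {
  if (!inherits(config, "eyeblink_sim_config"))
    stopf("`config` must be an eyeblink_sim_config")
  if (!is_flag(traces)) stopf("`traces` must be TRUE or FALSE")
  set.seed(config$seed)
  groups <- names(config$activity_mean_per_group)
  n_paired <- config$trials_per_session[["paired"]]
  n_cs <- config$trials_per_session[["cs_only"]]
  n_trials <- n_paired + n_cs
  rows <- vector("list", length(groups) * config$n_mice_per_group)
  eyelid <- list()
  wheel <- list()
  k <- 0L
  for (g in groups) {
    for (m in seq_len(config$n_mice_per_group)) {
      mouse_id <- sprintf("%s_m%02d", g, m)
      activity <- rnorm_pos(1, config$activity_mean_per_group[[g]],
                            config$activity_sd, floor = 0.005)
      state <- 0.01
      mouse_rows <- vector("list", config$n_sessions)
      for (s in seq_len(config$n_sessions)) {
        type <- sample(rep(c("paired", "cs_only"), c(n_paired, n_cs)))
        speed <- rnorm_pos(n_trials, activity, 0.04, floor = 0)
        iti <- runif(n_trials, config$iti_range[1], config$iti_range[2])
        amp <- numeric(n_trials)
        st <- numeric(n_trials)
        for (i in seq_len(n_trials)) {
          st[i] <- state
          amp[i] <- clip01(state *
            (config$baseline_amplitude +
               config$speed_amplitude_slope * speed[i]) +
            rnorm(1, 0, config$noise_sd))
          if (type[i] == "paired")
            state <- state + config$acquisition_gain *
              (1 + config$speed_weight * speed[i]) * state * (1 - state)
        }
        trial_id <- sprintf("%s_s%02d_t%03d", mouse_id, s, seq_len(n_trials))
        mouse_rows[[s]] <- data.frame(
          mouse_id = mouse_id, group = g, session = s,
          trial_index = seq_len(n_trials), trial_type = type,
          cs_onset_s = config$cs_onset, isi_s = config$isi,
          us_present = type == "paired",
          us_duration_s = config$us_duration, iti_s = iti,
          speed_mps = speed, cr_amplitude = amp, learning_state = st,
          trace_ref = trial_id, wheel_ref = trial_id,
          stringsAsFactors = FALSE)
        if (traces) {
          for (i in seq_len(n_trials)) {
            eyelid[[trial_id[i]]] <- gen_eyelid_trace(
              amplitude = amp[i], trial_type = type[i], config = config,
              trial_id = trial_id[i])
            wheel[[trial_id[i]]] <- gen_wheel_trace(
              mean_speed = speed[i], duration = config$trace_duration,
              trial_id = trial_id[i])
          }
        }
      }
      k <- k + 1L
      rows[[k]] <- do.call(rbind, mouse_rows)
    }
  }
  out <- list(trials = do.call(rbind, rows), config = config)
  rownames(out$trials) <- NULL
  if (traces) {
    out$eyelid <- eyelid
    out$wheel <- wheel
  }
  class(out) <- "eyeblink_cohort"
  out
}

#' @export
print.eyeblink_cohort <- function(x, ...) {
  cat(sprintf(
    "<eyeblink_cohort> %d trials, %d mice, %d sessions%s\n",
    nrow(x$trials), length(unique(x$trials$mouse_id)),
    max(x$trials$session),
    if (is.null(x$eyelid)) " (trial table only)" else " (+ traces)"))
  invisible(x)
}

# Render one normalized eyelid trace: a Gaussian CR ramp peaking at the
# expected US time (CS onset + ISI) and, on paired trials, a UR plateau at
# full closure from US onset, decaying after stimulus offset.
gen_eyelid_trace <- function(amplitude, trial_type, config,
                             trial_id = NULL, trace_noise_sd = 0.005) {
  t <- seq(0, config$trace_duration - 1 / config$sampling_rate,
           by = 1 / config$sampling_rate)
  us_time <- config$cs_onset + config$isi
  cr <- amplitude * exp(-((t - us_time) / (config$isi / 4))^2)
  v <- cr
  if (trial_type == "paired") {
    ur_on <- us_time + 0.010
    ur_off <- us_time + config$us_duration + 0.050
    ur <- ifelse(t >= ur_on & t <= ur_off, 1,
                 ifelse(t > ur_off, exp(-(t - ur_off) / 0.1), 0))
    v <- pmax(cr, ur)
  }
  if (trace_noise_sd > 0) v <- v + rnorm(length(t), 0, trace_noise_sd)
  eyelid_trace(clip01(v), config$sampling_rate, trial_id = trial_id)
}

# Wheel-speed trace for one trial: non-negative samples around the trial
# mean speed.
gen_wheel_trace <- function(mean_speed, duration, rate = 100,
                            trial_id = NULL, sd = 0.01) {
  n <- round(duration * rate)
  structure(list(values = rnorm_pos(n, mean_speed, sd),
                 sampling_rate = rate, trial_id = trial_id),
            class = "wheel_trace")
}

#' Simulate trial-level amplitude-speed data with known mixed-model truth
#'
#' Generates the textbook random-slopes, random-intercepts data-generating
#' process used to calibrate [fit_speed_amplitude_mixed()]: per-mouse
#' intercept and slope deviations are Gaussian around the fixed effects,
#' and trial noise is i.i.d. Gaussian. Unlike [gen_eyeblink_cohort()],
#' whose learning dynamics couple amplitude to speed history, this
#' generator matches the fitted model exactly, so confidence-interval
#' coverage and type-I error of the slope test can be measured against
#' known truth.
#'
#' @param n_mice,n_trials Cohort size.
#' @param intercept,slope Fixed effects (closure units; slope per m/s).
#' @param sd_intercept,sd_slope Between-mouse SDs of the random effects.
#' @param sd_noise Residual SD, closure units.
#' @param speed_mean,speed_sd Between-mouse distribution of mean walking
#'   speed, m/s.
#' @param trial_speed_sd Within-mouse trial-to-trial speed SD, m/s.
#' @param seed Integer seed.
#' @return A data frame with `mouse_id`, `speed`, `amplitude`.
#' @export
sim_mixed_trials <- function(n_mice = 10, n_trials = 200,
                             intercept = 0.2, slope = 0.5,
                             sd_intercept = 0.05, sd_slope = 0.1,
                             sd_noise = 0.05,
                             speed_mean = 0.08, speed_sd = 0.03,
                             trial_speed_sd = 0.02, seed = 1L) {
  set.seed(assert_seed(seed))
  n_mice <- assert_count(n_mice, "n_mice")
  n_trials <- assert_count(n_trials, "n_trials")
  mouse <- rep(sprintf("m%02d", seq_len(n_mice)), each = n_trials)
  mu <- rnorm_pos(n_mice, speed_mean, speed_sd, floor = 0.005)
  u0 <- rnorm(n_mice, 0, sd_intercept)
  u1 <- rnorm(n_mice, 0, sd_slope)
  idx <- rep(seq_len(n_mice), each = n_trials)
  speed <- rnorm_pos(n_mice * n_trials, mu[idx], trial_speed_sd)
  amplitude <- (intercept + u0[idx]) + (slope + u1[idx]) * speed +
    rnorm(n_mice * n_trials, 0, sd_noise)
  data.frame(mouse_id = mouse, speed = speed, amplitude = amplitude,
             stringsAsFactors = FALSE)
}
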