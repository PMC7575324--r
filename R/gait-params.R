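# x position of a paw in the ground frame (mm): on a treadmill the belt
# carries the ground backward at belt speed, so belt compensation adds
# belt_speed * t; overground tracks are already in the ground frame.
ground_x <- function(tracks, paw, frame = c("ground", "belt")) {
  frame <- match.arg(frame)
  x <- tracks$paws[[paw]]$x
  if (tracks$context == "treadmill" && frame == "ground") {
    v <- tracks$belt_speed[[paw_side(paw)]]
    if (!is.finite(v)) stopf("treadmill tracks need a belt speed")
    x <- x + 1000 * v * tracks$time
  }
  x
}

time_index <- function(tracks, t)
  pmin(pmax(round(t * tracks$frame_rate) + 1L, 1L), length(tracks$time))

#' Individual-limb gait parameters per stride
#'
#' Computes, for every complete stride (stance onset to next stance onset
#' with one intervening swing onset): stride duration (s), cadence (1/s,
#' the inverse of stride duration), duty factor (stance duration over
#' stride duration), stride length (forward displacement from touch-down
#' to touch-down, mm) and swing velocity (forward displacement during
#' swing divided by swing duration, m/s). Displacements are measured in
#' the ground frame; on a treadmill this belt-compensates the x axis
#' (set `frame = "belt"` for raw treadmill-frame displacements).
#' Incomplete strides at the recording boundary are dropped; the count is
#' attached as attribute `"n_dropped"`.
#'
#' @param strides A [segment_strides()] result.
#' @param tracks The [paw_tracks()] the strides came from.
#' @param frame `"ground"` (default) or `"belt"`.
#' @return A data frame, one row per stride: `paw`, `stride`,
#'   `stance_onset_s`, `stride_duration_s`, `cadence_hz`, `duty_factor`,
#'   `stride_length_mm`, `swing_velocity_mps`, `stance_duration_s`,
#'   `swing_duration_s`.
#' @export
limb_params <- function(strides, tracks, frame = c("ground", "belt")) {
  frame <- match.arg(frame)
  st <- strides$stance_onset
  sw <- strides$swing_onset
  n_dropped <- 0L
  rows <- list()
  if (length(st) >= 2L) {
    xg <- ground_x(tracks, strides$paw, frame)
    for (i in seq_len(length(st) - 1L)) {
      t0 <- st[i]; t1 <- st[i + 1L]
      lift <- sw[sw > t0 & sw < t1]
      if (length(lift) != 1L) { n_dropped <- n_dropped + 1L; next }
      dur <- t1 - t0
      stance_dur <- lift - t0
      i0 <- time_index(tracks, t0); i1 <- time_index(tracks, t1)
      il <- time_index(tracks, lift)
      rows[[length(rows) + 1L]] <- data.frame(
        paw = strides$paw, stride = i, stance_onset_s = t0,
        stride_duration_s = dur, cadence_hz = 1 / dur,
        duty_factor = stance_dur / dur,
        stride_length_mm = xg[i1] - xg[i0],
        swing_velocity_mps = (xg[i1] - xg[il]) / 1000 / (t1 - lift),
        stance_duration_s = stance_dur, swing_duration_s = t1 - lift)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(paw = character(0), stride = integer(0),
               stance_onset_s = numeric(0), stride_duration_s = numeric(0),
               cadence_hz = numeric(0), duty_factor = numeric(0),
               stride_length_mm = numeric(0),
               swing_velocity_mps = numeric(0),
               stance_duration_s = numeric(0), swing_duration_s = numeric(0))
  attr(out, "n_dropped") <- n_dropped
  out
}

HOMOLOG <- c(FR = "FL", FL = "FR", HR = "HL", HL = "HR")

#' Interlimb and whole-body coordination parameters
#'
#' Computes the coordination parameters per stride:
#' \describe{
#'   \item{step length}{forward displacement of a paw relative to its
#'     contralateral homolog at that paw's stance onset (mm).}
#'   \item{stance phase}{relative timing of each paw's touch-down within
#'     the stride cycle of the reference paw (FR by default),
#'     `(stance_time - stance_time_ref) / stride_duration`, wrapped to
#'     \[0, 1).}
#'   \item{base of support}{lateral width between the two front and the
#'     two hind paws during stance (mm).}
#'   \item{double support}{percentage of the stride cycle from a paw's
#'     touch-down to its contralateral homolog's lift-off.}
#'   \item{center of oscillation}{midpoint of a limb's stance-onset and
#'     swing-onset forward positions, relative to the body center (mm).}
#'   \item{supports}{fraction of the reference stride spent in each
#'     support configuration, from per-frame paw-ground contact
#'     (z below `contact_height`): 3-paw, 2-paw diagonal, 2-paw
#'     non-diagonal, and an `other` bucket (4-, 1- and 0-paw) so the
#'     categories partition every frame.}
#' }
#' Paws without segmented strides yield missing entries for their pairs;
#' the remaining parameters are still computed.
#'
#' @param strides_list Named list of [segment_strides()] results (one per
#'   paw; missing paws allowed).
#' @param tracks The [paw_tracks()] object.
#' @param reference_paw Reference paw for stance phase and supports.
#' @param contact_height Ground-contact threshold on z, mm.
#' @return A list of data frames: `step_length`, `stance_phase`,
#'   `base_of_support`, `double_support`, `center_of_oscillation`,
#'   `supports`.
#' @export
interlimb_params <- function(strides_list, tracks, reference_paw = "FR",
                             contact_height = 1) {
  paws <- names(strides_list)
  ref <- strides_list[[reference_paw]]
  if (is.null(ref)) stopf("reference paw %s has no strides", reference_paw)

  # step length and double support: per limb at its own stance onsets
  step_rows <- ds_rows <- co_rows <- list()
  for (p in paws) {
    s <- strides_list[[p]]
    if (n_strides(s) < 1L) next
    q <- HOMOLOG[[p]]
    xq <- if (q %in% paws) tracks$paws[[q]]$x else NULL
    sq <- strides_list[[q]]
    xp <- tracks$paws[[p]]$x
    x_rel <- xp - tracks$body_x
    for (i in seq_len(length(s$stance_onset) - 1L)) {
      t0 <- s$stance_onset[i]; t1 <- s$stance_onset[i + 1L]
      dur <- t1 - t0
      i0 <- time_index(tracks, t0)
      if (!is.null(xq))
        step_rows[[length(step_rows) + 1L]] <- data.frame(
          paw = p, stride = i, step_length_mm = xp[i0] - xq[i0])
      if (!is.null(sq) && length(sq$swing_onset)) {
        lift_q <- sq$swing_onset[sq$swing_onset >= t0]
        if (length(lift_q))
          ds_rows[[length(ds_rows) + 1L]] <- data.frame(
            paw = p, stride = i,
            double_support_pct = 100 * ((lift_q[1] - t0) %% dur) / dur)
      }
      lift <- s$swing_onset[s$swing_onset > t0 & s$swing_onset < t1]
      if (length(lift) == 1L) {
        il <- time_index(tracks, lift)
        co_rows[[length(co_rows) + 1L]] <- data.frame(
          paw = p, stride = i,
          center_of_oscillation_mm = (x_rel[i0] + x_rel[il]) / 2)
      }
    }
  }

  # stance phase, base of support, supports: per reference stride
  ph_rows <- bos_rows <- sup_rows <- list()
  contact <- vapply(PAW_NAMES, function(p)
    tracks$paws[[p]]$z < contact_height, logical(length(tracks$time)))
  if (n_strides(ref) >= 1L) {
    for (i in seq_len(length(ref$stance_onset) - 1L)) {
      t0 <- ref$stance_onset[i]; t1 <- ref$stance_onset[i + 1L]
      dur <- t1 - t0
      for (p in setdiff(paws, reference_paw)) {
        s <- strides_list[[p]]
        if (is.null(s) || !length(s$stance_onset)) next
        tp <- s$stance_onset[s$stance_onset >= t0 & s$stance_onset < t1]
        if (length(tp))
          ph_rows[[length(ph_rows) + 1L]] <- data.frame(
            paw = p, stride = i,
            pair = if (p == HOMOLOG[[reference_paw]]) "left-right" else
              if (substr(p, 1, 1) != substr(reference_paw, 1, 1) &&
                  paw_side(p) == paw_side(reference_paw)) "front-hind" else
                "diagonal",
            stance_phase = ((tp[1] - t0) / dur) %% 1)
      }
      fr_idx <- time_index(tracks, t0):time_index(tracks, t1)
      both_front <- contact[fr_idx, "FR"] & contact[fr_idx, "FL"]
      both_hind <- contact[fr_idx, "HR"] & contact[fr_idx, "HL"]
      bos_rows[[length(bos_rows) + 1L]] <- data.frame(
        stride = i,
        front_mm = if (any(both_front))
          mean(abs(tracks$paws$FR$y[fr_idx] -
                     tracks$paws$FL$y[fr_idx])[both_front]) else NA_real_,
        hind_mm = if (any(both_hind))
          mean(abs(tracks$paws$HR$y[fr_idx] -
                     tracks$paws$HL$y[fr_idx])[both_hind]) else NA_real_)
      cc <- contact[fr_idx, , drop = FALSE]
      ncon <- rowSums(cc)
      diag2 <- ncon == 2L & ((cc[, "FR"] & cc[, "HL"]) |
                               (cc[, "FL"] & cc[, "HR"]))
      sup_rows[[length(sup_rows) + 1L]] <- data.frame(
        stride = i,
        support_3paw = mean(ncon == 3L),
        support_2paw_diag = mean(diag2),
        support_2paw_other = mean(ncon == 2L & !diag2),
        support_other = mean(ncon %in% c(0L, 1L, 4L)))
    }
  }
  bind <- function(rows) if (length(rows)) do.call(rbind, rows) else NULL
  list(step_length = bind(step_rows), stance_phase = bind(ph_rows),
       base_of_support = bind(bos_rows), double_support = bind(ds_rows),
       center_of_oscillation = bind(co_rows), supports = bind(sup_rows))
}

#' Coefficient of variation
#'
#' All gait variability analyses are based on coefficients of variation,
#' `CV = sd / mean`.
#'
#' @param x Numeric sample of per-stride parameter values (>= 2 values,
#'   nonzero mean).
#' @return The coefficient of variation.
#' @examples
#' variability(c(1, 3))   # sd/mean = sqrt(2)/2
#' @export
variability <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) stopf("need >= 2 samples")
  if (any(!is.finite(x))) stopf("non-finite samples")
  m <- mean(x)
  if (abs(m) < .Machine$double.eps)
    stopf("CV is undefined for zero-mean samples")
  sd(x) / m
}
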