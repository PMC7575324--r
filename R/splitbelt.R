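#' Fast-minus-slow asymmetry of a gait parameter
#'
#' @param param_fast,param_slow Per-trial parameter values for the limb on
#'   the fast and the slow belt. Missing values propagate.
#' @return `param_fast - param_slow`.
#' @examples
#' asymmetry(0.05, 0.02)   # 0.03
#' @export
asymmetry <- function(param_fast, param_slow) {
  if (length(param_fast) != length(param_slow)) stopf("length mismatch")
  param_fast - param_slow
}

#' Build an adaptation series from per-trial asymmetries
#'
#' @param protocol A [splitbelt_protocol()].
#' @param values Per-trial asymmetry values (fast - slow), one per
#'   protocol trial.
#' @return An `adaptation_series` data frame (protocol columns plus
#'   `asymmetry`).
#' @export
adaptation_series <- function(protocol, values) {
  protocol <- validate_protocol(protocol)
  if (length(values) != nrow(protocol))
    stopf("series length (%d) must equal protocol length (%d)",
          length(values), nrow(protocol))
  if (any(!is.finite(values))) stopf("asymmetry values must be finite")
  out <- as.data.frame(protocol)
  out$asymmetry <- as.numeric(values)
  class(out) <- c("adaptation_series", "data.frame")
  out
}

#' Phase metrics of a split-belt adaptation series
#'
#' Reduces a per-trial asymmetry series to the three standard adaptation
#' quantities: the initial error (asymmetry on the first split trial),
#' the change over the split period (last split trial minus first split
#' trial), and the aftereffect. The aftereffect is the first washout
#' trial minus the baseline average (set `aftereffect_baseline = FALSE`
#' for the plain first-washout-trial variant).
#'
#' @param series An `adaptation_series` (e.g. [gen_splitbelt_series()]),
#'   or a data frame with `phase` and `asymmetry` columns.
#' @param aftereffect_baseline Subtract the baseline mean from the first
#'   washout trial (default), or report the raw first washout trial.
#' @return A list of class `"phase_metrics"`: `initial_error`,
#'   `change_over_split`, `aftereffect`.
#' @export
phase_metrics <- function(series, aftereffect_baseline = TRUE) {
  if (!all(c("phase", "asymmetry") %in% names(series)))
    stopf("series needs `phase` and `asymmetry` columns")
  need <- c(baseline = 1L, split = 2L, washout = 1L)
  for (ph in names(need))
    if (sum(series$phase == ph) < need[[ph]])
      stopf("series lacks the %s phase (need >= %d trial%s)", ph,
            need[[ph]], if (need[[ph]] > 1) "s" else "")
  base <- series$asymmetry[series$phase == "baseline"]
  split <- series$asymmetry[series$phase == "split"]
  wash <- series$asymmetry[series$phase == "washout"]
  structure(list(
    initial_error = split[1],
    change_over_split = split[length(split)] - split[1],
    aftereffect = if (aftereffect_baseline) wash[1] - mean(base) else
      wash[1]), class = "phase_metrics")
}

#' @export
print.phase_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<phase_metrics> initial error %.4f, change over split %+.4f,",
           " aftereffect %+.4f\n"),
    x$initial_error, x$change_over_split, x$aftereffect))
  invisible(x)
}

#' Learned change as a percent of the group initial error
#'
#' Normalizes each animal's change over split and aftereffect by the
#' group's average initial error, as percentages of magnitude: 100% means
#' complete adaptation. The sign convention flips changes over split and
#' aftereffects so that all three epochs are directly comparable in
#' magnitude before the ratio is taken.
#'
#' @param metrics_list List of [phase_metrics()] objects, one per animal
#'   of the group.
#' @return A list: `group_initial_error`, and data frame `per_animal`
#'   with `pct_change_over_split` and `pct_aftereffect`, plus group means
#'   `mean_pct_change_over_split`, `mean_pct_aftereffect`.
#' @examples
#' m <- structure(list(initial_error = -0.30, change_over_split = 0.25,
#'                     aftereffect = 0.22), class = "phase_metrics")
#' percent_of_initial_error(list(m))   # 83.3% and 73.3%
#' @export
percent_of_initial_error <- function(metrics_list) {
  if (inherits(metrics_list, "phase_metrics"))
    metrics_list <- list(metrics_list)
  if (!length(metrics_list)) stopf("no phase metrics supplied")
  ie <- vapply(metrics_list, `[[`, numeric(1), "initial_error")
  group_ie <- mean(ie)
  if (abs(group_ie) < .Machine$double.eps)
    stopf("group mean initial error is zero; percent change is undefined")
  ch <- vapply(metrics_list, `[[`, numeric(1), "change_over_split")
  ae <- vapply(metrics_list, `[[`, numeric(1), "aftereffect")
  per <- data.frame(
    initial_error = ie,
    pct_change_over_split = 100 * abs(ch) / abs(group_ie),
    pct_aftereffect = 100 * abs(ae) / abs(group_ie))
  list(group_initial_error = group_ie, per_animal = per,
       mean_pct_change_over_split = mean(per$pct_change_over_split),
       mean_pct_aftereffect = mean(per$pct_aftereffect))
}

#' Stance-speed compliance during split-belt walking
#'
#' Checks that an animal actually walked the imposed belt speeds during
#' the split period: for each split trial, the stance speed of each side
#' (mean absolute backward x velocity of the paw during stance, treadmill
#' frame) must match that side's belt speed within `tolerance` (a
#' fraction of the belt speed); the animal passes if at least
#' `min_fraction` of split trials comply on both sides.
#'
#' @param trial_tracks Named list of [paw_tracks()] objects, one per
#'   split trial.
#' @param protocol The [splitbelt_protocol()]; its split trials must
#'   correspond (in order) to `trial_tracks`.
#' @param paws Two paws used to measure the two sides (front pair by
#'   default).
#' @param tolerance Allowed relative deviation from belt speed.
#' @param min_fraction Minimum fraction of compliant split trials.
#' @return A list of class `"compliance_result"`: `pass`,
#'   `fraction_compliant`, and per-trial data frame `trials`
#'   (`trial`, `speed_left`, `speed_right`, `belt_left`, `belt_right`,
#'   `compliant`).
#' @export
stance_speed_compliance <- function(trial_tracks, protocol,
                                    paws = c("FL", "FR"),
                                    tolerance = 0.2, min_fraction = 0.8) {
  protocol <- validate_protocol(protocol)
  split_proto <- protocol[protocol$phase == "split", ]
  if (nrow(split_proto) == 0L) stopf("protocol has no split trials")
  if (length(trial_tracks) != nrow(split_proto))
    stopf("need tracks for each of the %d split trials", nrow(split_proto))
  rows <- list()
  for (i in seq_along(trial_tracks)) {
    trk <- trial_tracks[[i]]
    sp <- setNames(numeric(2), c("left", "right"))
    for (p in paws) {
      s <- segment_strides(trk, p)
      if (n_strides(s) < 1L)
        stopf("no strides segmented on paw %s of split trial %d", p, i)
      x <- trk$paws[[p]]$x
      v <- c(NA, diff(x)) * trk$frame_rate / 1000  # m/s, treadmill frame
      stance <- rep(FALSE, length(x))
      for (k in seq_len(length(s$stance_onset) - 1L)) {
        t0 <- s$stance_onset[k]
        lift <- s$swing_onset[s$swing_onset > t0][1]
        if (is.na(lift)) next
        stance[time_index(trk, t0):time_index(trk, lift)] <- TRUE
      }
      sp[[paw_side(p)]] <- mean(abs(v[stance]), na.rm = TRUE)
    }
    belts <- c(left = NA_real_, right = NA_real_)
    # slow belt drives one side, fast the other; sides are matched by speed
    belts[names(which.min(sp))] <- split_proto$speed_slow[i]
    belts[names(which.max(sp))] <- split_proto$speed_fast[i]
    ok <- all(abs(sp - belts) <= tolerance * belts)
    rows[[i]] <- data.frame(
      trial = split_proto$trial[i], speed_left = sp[["left"]],
      speed_right = sp[["right"]], belt_left = belts[["left"]],
      belt_right = belts[["right"]], compliant = ok)
  }
  trials <- do.call(rbind, rows)
  frac <- mean(trials$compliant)
  structure(list(pass = frac >= min_fraction, fraction_compliant = frac,
                 trials = trials), class = "compliance_result")
}

#' @export
print.compliance_result <- function(x, ...) {
  cat(sprintf("<compliance_result> %s (%.0f%% of split trials compliant)\n",
              if (x$pass) "PASS" else "FAIL", 100 * x$fraction_compliant))
  invisible(x)
}

#' Mixed-model genotype-by-phase analysis of adaptation metrics
#'
#' Tests for fixed effects of group (genotype) and experimental phase on
#' per-animal adaptation metrics, with animal as a random effect and one
#' observation per animal per phase level (initial error, change over
#' split, aftereffect). Post-hoc group contrasts within each phase use
#' Tukey-adjusted t-tests.
#'
#' @param metrics Data frame with one row per animal and phase:
#'   `animal`, `group`, `phase`, `value`.
#' @return A list of class `"genotype_phase_fit"`: the `model`
#'   (lmerTest fit), `anova` (Satterthwaite F table), `emmeans`
#'   (group means within phase) and `contrasts` (Tukey-adjusted group
#'   contrasts within phase, as a data frame).
#' @export
genotype_phase_model <- function(metrics) {
  need <- c("animal", "group", "phase", "value")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  metrics$group <- as.factor(metrics$group)
  metrics$phase <- as.factor(metrics$phase)
  if (nlevels(metrics$group) < 2L) stopf("need >= 2 groups")
  if (min(table(metrics$group)) / nlevels(metrics$phase) < 2)
    stopf("need >= 2 animals per group")
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  m <- suppressMessages(lmerTest::lmer(
    value ~ group * phase + (1 | animal), data = metrics, control = ctrl))
  em <- emmeans::emmeans(m, ~ group | phase)
  ct <- as.data.frame(summary(
    emmeans::contrast(em, method = "pairwise"), adjust = "tukey"))
  structure(list(model = m, anova = stats::anova(m), emmeans = em,
                 contrasts = ct), class = "genotype_phase_fit")
}

#' @export
print.genotype_phase_fit <- function(x, ...) {
  cat("<genotype_phase_fit> Tukey-adjusted group contrasts by phase:\n")
  print(x$contrasts, digits = 3)
  invisible(x)
}
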