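#' Classify a conditioned response on one trial
#'
#' Applies the CR rule to a normalized eyelid trace: the trial contains a
#' CR if eyelid closure reaches at least `threshold` (default 0.1
#' normalized units) within the response window, which opens 100 ms after
#' CS onset and closes at US onset (exclusive). On CS-only trials the
#' window instead extends through the time the US would have occupied
#' (CS onset + ISI + US duration, inclusive), and the peak time of the
#' response is reported.
#'
#' @param trace An [eyelid_trace()] (normalized closure in \[0, 1\]).
#' @param cs_onset CS onset, seconds from trace start.
#' @param isi CS-to-US onset interval, seconds.
#' @param trial_type `"paired"` or `"cs_only"`.
#' @param us_duration US duration, seconds (extends the CS-only window).
#' @param threshold CR amplitude threshold, normalized closure.
#' @return A list of class `"cr_result"`: `is_cr`, `amplitude` (max
#'   closure in the window, whether or not it crosses threshold),
#'   `peak_time` (s after CS onset; CS-only trials), `window` (c(start,
#'   end), s from trace start).
#' @examples
#' tr <- eyelid_trace(c(rep(0, 200), seq(0, .4, length.out = 100),
#'                      rep(0, 150)), sampling_rate = 900)
#' classify_cr(tr, cs_onset = 0.1, isi = 0.3)
#' @export
classify_cr <- function(trace, cs_onset, isi,
                        trial_type = c("paired", "cs_only"),
                        us_duration = 0.050, threshold = 0.1) {
  trial_type <- match.arg(trial_type)
  if (!inherits(trace, "eyelid_trace"))
    stopf("`trace` must be a normalized eyelid_trace")
  assert_scalar_num(cs_onset, "cs_onset", 0)
  assert_scalar_num(isi, "isi", 0, strict_lower = TRUE)
  us_onset <- cs_onset + isi
  win_end <- if (trial_type == "paired") us_onset else
    us_onset + us_duration
  times <- trace_times(trace)
  if (max(times) < win_end - 1e-9)
    stopf("trace (%.3f s) shorter than the response window end (%.3f s)",
          max(times), win_end)
  eps <- 1e-9
  lower <- cs_onset + 0.100
  sel <- if (trial_type == "paired")
    times >= lower - eps & times < us_onset - eps
  else
    times >= lower - eps & times <= win_end + eps
  if (!any(sel)) stopf("no samples fall inside the response window")
  amp <- max(trace$values[sel])
  peak <- if (trial_type == "cs_only")
    times[sel][which.max(trace$values[sel])] - cs_onset else NA_real_
  structure(list(is_cr = amp >= threshold - 1e-12, amplitude = amp,
                 peak_time = peak, window = c(lower, win_end),
                 trial_type = trial_type),
            class = "cr_result")
}

#' @export
print.cr_result <- function(x, ...) {
  cat(sprintf("<cr_result> %s: amplitude %.3f%s (window %.3f-%.3f s)\n",
              if (x$is_cr) "CR" else "no CR", x$amplitude,
              if (!is.na(x$peak_time))
                sprintf(", peak %+.0f ms after CS", 1000 * x$peak_time)
              else "", x$window[1], x$window[2]))
  invisible(x)
}

#' Classify every trial of a cohort
#'
#' Convenience wrapper applying [classify_cr()] to each row of a trial
#' table. When the cohort carries eyelid traces they are used; otherwise
#' the stored `cr_amplitude` column is thresholded directly (the window
#' rule is then the generator's responsibility).
#'
#' @param cohort An `eyeblink_cohort` (or a list with `trials` and
#'   optionally `eyelid`).
#' @param threshold CR amplitude threshold.
#' @return The trial table with `is_cr`, `amplitude` and `peak_time`
#'   columns appended.
#' @export
classify_cr_trials <- function(cohort, threshold = 0.1) {
  trials <- cohort$trials
  if (is.null(trials)) stopf("cohort has no trial table")
  if (!is.null(cohort$eyelid)) {
    res <- lapply(seq_len(nrow(trials)), function(i) {
      classify_cr(cohort$eyelid[[trials$trace_ref[i]]],
                  cs_onset = trials$cs_onset_s[i], isi = trials$isi_s[i],
                  trial_type = trials$trial_type[i],
                  us_duration = trials$us_duration_s[i],
                  threshold = threshold)
    })
    trials$is_cr <- vapply(res, `[[`, logical(1), "is_cr")
    trials$amplitude <- vapply(res, `[[`, numeric(1), "amplitude")
    trials$peak_time <- vapply(res, `[[`, numeric(1), "peak_time")
  } else {
    trials$is_cr <- trials$cr_amplitude >= threshold - 1e-12
    trials$amplitude <- trials$cr_amplitude
    trials$peak_time <- NA_real_
  }
  trials
}

#' Percent conditioned responses in a session
#'
#' @param is_cr Logical vector of per-trial CR classifications for the
#'   eligible trials of one session (by default all CS-bearing trials,
#'   paired and CS-only alike, are eligible).
#' @return Percentage in \[0, 100\].
#' @export
percent_cr <- function(is_cr) {
  if (length(is_cr) == 0L) stopf("empty session: no eligible trials")
  if (!is.logical(is_cr) || any(is.na(is_cr)))
    stopf("`is_cr` must be TRUE/FALSE per trial")
  100 * sum(is_cr) / length(is_cr)
}

#' Per-session learning curve and learning onset
#'
#' `learning_curve()` aggregates classified trials into per-session %CR
#' and mean CR amplitude; `learning_onset()` returns the first session
#' whose mean CR amplitude strictly exceeds the threshold (0.1 normalized
#' units), or `NA` if learning never reaches it.
#'
#' @param trials Classified trial table (see [classify_cr_trials()]) for
#'   one mouse, with `session`, `is_cr`, `amplitude`.
#' @return `learning_curve()`: data frame with `session`, `pct_cr`,
#'   `mean_amplitude`, `n_trials`. `learning_onset()`: integer session
#'   index or `NA_integer_`.
#' @export
learning_curve <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0L) stopf("empty trial table")
  sp <- split(trials, trials$session)
  out <- data.frame(
    session = as.integer(names(sp)),
    pct_cr = vapply(sp, function(d) percent_cr(d$is_cr), numeric(1)),
    mean_amplitude = vapply(sp, function(d) mean(d$amplitude), numeric(1)),
    n_trials = vapply(sp, nrow, integer(1)))
  rownames(out) <- NULL
  out[order(out$session), ]
}

#' @rdname learning_curve
#' @param mean_amplitudes Per-session mean CR amplitudes in session order
#'   (e.g. `learning_curve(trials)$mean_amplitude`).
#' @param threshold Onset threshold on the session mean amplitude.
#' @export
learning_onset <- function(mean_amplitudes, threshold = 0.1) {
  if (length(mean_amplitudes) == 0L) stopf("no sessions")
  if (any(!is.finite(mean_amplitudes))) stopf("non-finite session amplitude")
  idx <- which(mean_amplitudes > threshold)
  if (length(idx) == 0L) NA_integer_ else as.integer(idx[1])
}

#' Locomotor state of a trial
#'
#' Summarizes a wheel/treadmill speed signal over a trial window:
#' distance walked (time integral of speed, trapezoidal), mean speed,
#' fraction of time spent walking (speed above `walking_threshold`), and
#' the stationary/ambulatory call. A trial is stationary iff its mean
#' speed is below 0.05 m/s.
#'
#' @param speed Speed samples, m/s (non-negative).
#' @param times Sample times, s (or give `sampling_rate`).
#' @param sampling_rate Sampling rate, Hz (used when `times` is `NULL`).
#' @param window Optional `c(start, end)` restriction, s.
#' @param stationary_threshold Mean-speed cutoff, m/s.
#' @param walking_threshold Instantaneous-speed cutoff for
#'   `fraction_time_walking`, m/s.
#' @return A list of class `"locomotor_state"`: `mean_speed`, `distance`,
#'   `fraction_time_walking`, `is_stationary`, `is_ambulatory`.
#' @examples
#' locomotor_state(rep(0.12, 601), sampling_rate = 10)   # 7.2 m over 60 s
#' @export
locomotor_state <- function(speed, times = NULL, sampling_rate = NULL,
                            window = NULL, stationary_threshold = 0.05,
                            walking_threshold = 0.01) {
  if (!is.numeric(speed) || length(speed) < 2L)
    stopf("`speed` must be a numeric series")
  if (any(!is.finite(speed))) stopf("non-finite speed values")
  if (any(speed < 0)) stopf("negative speeds are invalid")
  if (is.null(times)) {
    if (is.null(sampling_rate)) stopf("give `times` or `sampling_rate`")
    times <- (seq_along(speed) - 1) / sampling_rate
  }
  if (length(times) != length(speed)) stopf("times/speed length mismatch")
  if (!is.null(window)) {
    keep <- times >= window[1] - 1e-9 & times <= window[2] + 1e-9
    if (sum(keep) < 2L) stopf("window does not cover the speed series")
    times <- times[keep]; speed <- speed[keep]
  }
  distance <- pracma::trapz(times, speed)
  span <- diff(range(times))
  mean_speed <- distance / span
  structure(list(
    mean_speed = mean_speed, distance = distance,
    fraction_time_walking = mean(speed > walking_threshold),
    is_stationary = mean_speed < stationary_threshold,
    is_ambulatory = mean_speed >= stationary_threshold),
    class = "locomotor_state")
}

#' @export
print.locomotor_state <- function(x, ...) {
  cat(sprintf(
    "<locomotor_state> mean %.3f m/s, %.2f m, %.0f%% walking (%s)\n",
    x$mean_speed, x$distance, 100 * x$fraction_time_walking,
    if (x$is_stationary) "stationary" else "ambulatory"))
  invisible(x)
}

#' Speed-binned CR amplitudes with per-genotype trial histograms
#'
#' Bins trials by walking speed per animal, averages the per-animal bin
#' means across animals, and reports the per-animal percentage of trials
#' in each bin (each animal's histogram sums to 100%), averaged across
#' animals. Bins with no trials for any animal are reported as missing,
#' not zero.
#'
#' @param trials Data frame with `mouse_id`, `speed`, `amplitude` (use
#'   the columns of a classified cohort, e.g. `speed = speed_mps`).
#' @param bin_edges Strictly increasing bin edges, m/s. Intervals are
#'   left-closed, and the last is closed on both sides.
#' @return A list: `summary` (data frame `bin_low`, `bin_high`,
#'   `bin_center`, `mean_amplitude`, `pct_trials`), `amplitude_by_animal`
#'   and `pct_by_animal` (animals x bins matrices).
#' @export
speed_binned_amplitude <- function(trials, bin_edges) {
  if (nrow(trials) == 0L) stopf("no trials")
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE))
    stopf("`bin_edges` must be strictly increasing")
  nb <- length(bin_edges) - 1L
  animals <- unique(trials$mouse_id)
  amp <- pct <- matrix(NA_real_, length(animals), nb,
                       dimnames = list(animals, NULL))
  for (a in animals) {
    d <- trials[trials$mouse_id == a, ]
    bin <- cut(d$speed, bin_edges, right = FALSE, include.lowest = TRUE,
               labels = FALSE)
    ok <- !is.na(bin)
    cnt <- tabulate(bin[ok], nbins = nb)
    pct[a, ] <- 100 * cnt / sum(cnt)
    for (b in which(cnt > 0))
      amp[a, b] <- mean(d$amplitude[ok][bin[ok] == b])
  }
  mean_amp <- colMeans(amp, na.rm = TRUE)
  mean_amp[!is.finite(mean_amp)] <- NA_real_
  list(summary = data.frame(
    bin_low = bin_edges[-length(bin_edges)], bin_high = bin_edges[-1],
    bin_center = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
    mean_amplitude = mean_amp,
    pct_trials = colMeans(pct)),
    amplitude_by_animal = amp, pct_by_animal = pct)
}

#' Single-trial learning: amplitude after puff vs after no-puff trials
#'
#' For 50%-US test sessions, partitions trials by whether the previous
#' trial in the same session carried an air-puff US (the first trial of
#' each session is excluded), and compares CR amplitudes on the two kinds
#' of trials, per animal.
#'
#' @param trials Data frame with `mouse_id`, `session`, `trial_index`,
#'   `us_present` (logical) and `amplitude`, in trial order.
#' @return A list: `per_animal` (data frame `mouse_id`, `after_puff`,
#'   `after_no_puff`, `difference`), and group means
#'   `mean_after_puff`, `mean_after_no_puff`, `mean_difference`.
#' @export
single_trial_modulation <- function(trials) {
  need <- c("mouse_id", "session", "trial_index", "us_present", "amplitude")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  trials <- trials[order(trials$mouse_id, trials$session,
                         trials$trial_index), ]
  sp <- split(trials, interaction(trials$mouse_id, trials$session,
                                  drop = TRUE))
  if (any(vapply(sp, nrow, integer(1)) < 2L))
    stopf("single-trial sessions have no previous-trial history")
  parts <- lapply(sp, function(d) {
    data.frame(mouse_id = d$mouse_id[-1],
               prev_us = d$us_present[-nrow(d)],
               amplitude = d$amplitude[-1])
  })
  dd <- do.call(rbind, parts)
  per <- do.call(rbind, lapply(split(dd, dd$mouse_id), function(d) {
    data.frame(mouse_id = d$mouse_id[1],
               after_puff = mean(d$amplitude[d$prev_us]),
               after_no_puff = mean(d$amplitude[!d$prev_us]))
  }))
  per$difference <- per$after_puff - per$after_no_puff
  rownames(per) <- NULL
  list(per_animal = per,
       mean_after_puff = mean(per$after_puff, na.rm = TRUE),
       mean_after_no_puff = mean(per$after_no_puff, na.rm = TRUE),
       mean_difference = mean(per$difference, na.rm = TRUE))
}

#' CR timing on CS-only trials
#'
#' Summarizes when CRs peak relative to CS onset on CS-only trials (where
#' no reflex blink masks the response); well-timed CRs peak around the
#' time the US would have been delivered (the ISI).
#'
#' @param trials Classified CS-only trial table with `mouse_id`, `is_cr`,
#'   `peak_time` (from [classify_cr_trials()] on a cohort with traces).
#' @return A list: `per_trial` (CR trials with peak times), `per_animal`
#'   (mean/median peak time per animal), `mean_peak_time` (grand mean
#'   across animals; `NA` when no CRs). Trials without a CR are ignored;
#'   with no CR trials at all, the summaries are empty.
#' @export
cr_timing <- function(trials) {
  cr <- trials[trials$is_cr & !is.na(trials$peak_time), , drop = FALSE]
  if (nrow(cr) == 0L)
    return(list(per_trial = cr,
                per_animal = data.frame(mouse_id = character(0),
                                        mean_peak = numeric(0),
                                        median_peak = numeric(0)),
                mean_peak_time = NA_real_))
  per <- do.call(rbind, lapply(split(cr, cr$mouse_id), function(d)
    data.frame(mouse_id = d$mouse_id[1], mean_peak = mean(d$peak_time),
               median_peak = median(d$peak_time), n_cr = nrow(d))))
  rownames(per) <- NULL
  list(per_trial = cr, per_animal = per,
       mean_peak_time = mean(per$mean_peak))
}
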