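# Local maxima with topographic prominence. pracma::findpeaks has no
# prominence criterion, so this is computed directly: for each strict
# local maximum, the bases are the minima between the peak and the
# nearest higher sample on each side (or the series end), and prominence
# is peak height above the higher base.
find_peaks_prominent <- function(x, min_prominence, min_distance = 1L) {
  n <- length(x)
  d <- diff(x)
  # candidate peaks: rising then falling (plateaus take the first sample)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[x[cand] > x[pmax(cand - 1L, 1L)]]
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- if (i > 1L) x[seq_len(i - 1L)] else numeric(0)
    hi_l <- which(left > x[i])
    base_l <- if (length(hi_l)) min(x[(max(hi_l) + 1L):(i - 1L)]) else
      min(left, x[i])
    right <- if (i < n) x[(i + 1L):n] else numeric(0)
    hi_r <- which(right > x[i])
    base_r <- if (length(hi_r)) min(x[(i + 1L):(i + min(hi_r) - 1L)]) else
      min(right, x[i])
    x[i] - max(base_l, base_r)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) <= 1L || min_distance <= 1L) return(keep)
  # enforce minimum separation, preferring higher peaks
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord)
    if (!length(sel) || all(abs(sel - i) >= min_distance))
      sel <- c(sel, i)
  sort(sel)
}

#' Segment a paw track into strides
#'
#' Detects stance onsets (touch-downs) and swing onsets (lift-offs) from
#' the paw's forward excursion relative to the body center, using peak
#' detection: a touch-down is a local maximum of the body-relative
#' forward position (the paw lands ahead of the body and then moves
#' backward relative to it) and a lift-off a local minimum. Peaks must
#' have a prominence of at least `prominence_frac` of the total excursion
#' and are separated by at least half the median inter-peak interval;
#' detected events are then forced to alternate (of two same-type
#' neighbors the more extreme survives).
#'
#' @param tracks A [paw_tracks()] object.
#' @param paw One of `"FR"`, `"FL"`, `"HR"`, `"HL"`.
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   signal excursion.
#' @return An object of class `"stride_set"`: `paw`, `stance_onset` and
#'   `swing_onset` times (s), `frame_rate`. A constant track yields zero
#'   strides (not an error); non-finite positions are an error.
#' @export
segment_strides <- function(tracks, paw, prominence_frac = 0.2) {
  if (!inherits(tracks, "paw_tracks")) stopf("`tracks` must be paw_tracks")
  if (!paw %in% PAW_NAMES) stopf("unknown paw '%s'", paw)
  x <- tracks$paws[[paw]]$x - tracks$body_x
  if (any(!is.finite(x))) stopf("track contains non-finite positions")
  empty <- structure(list(paw = paw, stance_onset = numeric(0),
                          swing_onset = numeric(0),
                          frame_rate = tracks$frame_rate),
                     class = "stride_set")
  excursion <- diff(range(x))
  if (excursion < .Machine$double.eps) return(empty)
  prom <- prominence_frac * excursion
  maxima <- find_peaks_prominent(x, prom)
  minima <- find_peaks_prominent(-x, prom)
  if (length(maxima) >= 3L) {
    min_dist <- floor(0.5 * median(diff(maxima)))
    maxima <- find_peaks_prominent(x, prom, min_dist)
    minima <- find_peaks_prominent(-x, prom, min_dist)
  }
  if (length(maxima) == 0L || length(minima) == 0L) return(empty)
  ev <- rbind(data.frame(idx = maxima, type = "stance"),
              data.frame(idx = minima, type = "swing"))
  ev <- ev[order(ev$idx), ]
  # enforce alternation: among runs of one type keep the most extreme
  keep <- rep(TRUE, nrow(ev))
  i <- 1L
  while (i < nrow(ev)) {
    j <- i
    while (j < nrow(ev) && ev$type[j + 1L] == ev$type[i]) j <- j + 1L
    if (j > i) {
      vals <- x[ev$idx[i:j]]
      best <- if (ev$type[i] == "stance") which.max(vals) else
        which.min(vals)
      drop <- setdiff(i:j, i + best - 1L)
      keep[drop] <- FALSE
    }
    i <- j + 1L
  }
  ev <- ev[keep, ]
  structure(list(
    paw = paw,
    stance_onset = tracks$time[ev$idx[ev$type == "stance"]],
    swing_onset = tracks$time[ev$idx[ev$type == "swing"]],
    frame_rate = tracks$frame_rate),
    class = "stride_set")
}

#' @export
print.stride_set <- function(x, ...) {
  cat(sprintf("<stride_set> %s: %d stance onsets, %d swing onsets\n",
              x$paw, length(x$stance_onset), length(x$swing_onset)))
  invisible(x)
}

n_strides <- function(strides) max(0L, length(strides$stance_onset) - 1L)
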