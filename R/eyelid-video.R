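#' Eyelid trace containers
#'
#' `raw_eyelid_trace()` holds the per-frame eyelid distance in pixels as
#' extracted from video; `eyelid_trace()` holds the session-normalized
#' closure signal, ranging from 0 (eye fully open) to 1 (full blink).
#'
#' @param values Numeric vector, one value per frame (pixels for raw
#'   traces; closure in \[0, 1\] for normalized traces).
#' @param sampling_rate Frames per second.
#' @param trial_id Optional trial identifier.
#' @return An object of class `"raw_eyelid_trace"` or `"eyelid_trace"`.
#' @export
raw_eyelid_trace <- function(values, sampling_rate, trial_id = NULL) {
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values)))
    stopf("trace values must be finite numbers")
  if (any(values < 0)) stopf("eyelid distances must be >= 0")
  assert_scalar_num(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  structure(list(values = as.numeric(values), sampling_rate = sampling_rate,
                 trial_id = trial_id), class = "raw_eyelid_trace")
}

#' @rdname raw_eyelid_trace
#' @export
eyelid_trace <- function(values, sampling_rate, trial_id = NULL) {
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values)))
    stopf("trace values must be finite numbers")
  if (any(values < 0 | values > 1))
    stopf("normalized closure must lie in [0, 1]")
  assert_scalar_num(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  structure(list(values = as.numeric(values), sampling_rate = sampling_rate,
                 trial_id = trial_id), class = "eyelid_trace")
}

trace_times <- function(trace)
  (seq_along(trace$values) - 1) / trace$sampling_rate

#' Extract the eyelid distance from one eye frame
#'
#' Binarizes the grayscale frame at `threshold` (Otsu's method when not
#' given), keeps the largest connected foreground component, fits an
#' ellipse to it by its second-order pixel moments, and returns the full
#' minor-axis length in pixels as the distance between eyelids. For a
#' component with pixel-coordinate covariance eigenvalues
#' `l1 >= l2`, the fitted full axes are `4 * sqrt(l1)` and `4 * sqrt(l2)`
#' (exact for a filled ellipse).
#'
#' @param frame 2-D numeric matrix of intensities in \[0, 1\].
#' @param threshold Binarization threshold; `NULL` for Otsu.
#' @return A list with `distance_px` (minor axis), `major_px`,
#'   `closed_eye` (`TRUE` when no usable foreground ellipse was found, in
#'   which case `distance_px` is 0) and `threshold`.
#' @export
extract_eyelid_distance <- function(frame, threshold = NULL) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stopf("`frame` must be a 2-D numeric matrix")
  if (any(!is.finite(frame))) stopf("frame contains non-finite values")
  if (is.null(threshold)) {
    rng <- range(frame)
    if (diff(rng) < .Machine$double.eps) {
      threshold <- rng[1]  # flat frame: nothing will survive thresholding
    } else {
      threshold <- EBImage::otsu(EBImage::Image(clip01(frame)))
    }
  }
  mask <- frame > threshold
  degenerate <- list(distance_px = 0, major_px = 0, closed_eye = TRUE,
                     threshold = threshold)
  if (!any(mask)) return(degenerate)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  biggest <- which.max(sizes)
  coords <- which(lab == biggest, arr.ind = TRUE)
  if (nrow(coords) < 3L) return(degenerate)
  ev <- eigen(stats::cov(coords), symmetric = TRUE, only.values = TRUE)$values
  minor <- 4 * sqrt(max(ev[2], 0))
  list(distance_px = minor, major_px = 4 * sqrt(max(ev[1], 0)),
       closed_eye = minor < 1, threshold = threshold)
}

#' Extract an eyelid-distance trace from a stack of frames
#'
#' @param frames A list of 2-D matrices or a 3-D array (`height x width x
#'   n_frames`).
#' @param sampling_rate Frames per second.
#' @param threshold Binarization threshold shared across frames; `NULL`
#'   computes Otsu's threshold on the first frame and reuses it.
#' @param trial_id Optional trial identifier.
#' @return A [raw_eyelid_trace()] with a `closed_eye` logical attribute
#'   per frame.
#' @export
extract_eyelid_trace <- function(frames, sampling_rate, threshold = NULL,
                                 trial_id = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.list(frames) || length(frames) == 0L)
    stopf("`frames` must be a non-empty list of matrices or a 3-D array")
  if (is.null(threshold))
    threshold <- extract_eyelid_distance(frames[[1]])$threshold
  res <- lapply(frames, extract_eyelid_distance, threshold = threshold)
  tr <- raw_eyelid_trace(vapply(res, `[[`, numeric(1), "distance_px"),
                         sampling_rate, trial_id = trial_id)
  attr(tr, "closed_eye") <- vapply(res, `[[`, logical(1), "closed_eye")
  tr
}

#' Normalize a session of eyelid traces
#'
#' Maps raw eyelid distances to closure values in \[0, 1\] (1 = full
#' blink, 0 = fully open) with anchors shared across the whole session:
#' the full-blink anchor `d_closed` is the 1st percentile of all frame
#' distances (full blinks occur on every paired trial), and the open-eye
#' anchor `d_open` is the 97.5th percentile of pre-CS baseline distances
#' when `cs_onset` is supplied (of all distances otherwise). Percentile
#' anchors, rather than extremes, guard against tracking glitches; the
#' probabilities are configurable. Closure is
#' `(d_open - d) / (d_open - d_closed)`, clipped to \[0, 1\] -- monotone
#' decreasing in raw distance.
#'
#' @param raw_traces List of [raw_eyelid_trace()] objects (one session).
#' @param cs_onset CS onset time in seconds, used to restrict the open-eye
#'   anchor to pre-CS baseline frames; `NULL` to use all frames.
#' @param anchors Optional explicit `c(open = , closed = )` anchor values,
#'   bypassing the percentile rule.
#' @param probs Anchor percentiles, `c(closed = 0.01, open = 0.975)`.
#' @return A list of [eyelid_trace()] objects, with the anchors attached
#'   as an `"anchors"` attribute.
#' @export
normalize_session <- function(raw_traces, cs_onset = NULL, anchors = NULL,
                              probs = c(closed = 0.01, open = 0.975)) {
  if (!is.list(raw_traces) || length(raw_traces) == 0L)
    stopf("`raw_traces` must be a non-empty list")
  values <- lapply(raw_traces, function(tr) {
    if (inherits(tr, c("raw_eyelid_trace", "eyelid_trace"))) tr$values
    else stopf("all elements must be eyelid traces")
  })
  all_v <- unlist(values)
  if (is.null(anchors)) {
    d_closed <- unname(quantile(all_v, probs[["closed"]]))
    base_v <- if (is.null(cs_onset)) all_v else
      unlist(lapply(raw_traces, function(tr)
        tr$values[trace_times(tr) < cs_onset]))
    if (length(base_v) == 0L)
      stopf("no pre-CS baseline frames before cs_onset = %g s", cs_onset)
    d_open <- unname(quantile(base_v, probs[["open"]]))
  } else {
    d_open <- anchors[["open"]]
    d_closed <- anchors[["closed"]]
  }
  if (isTRUE(all.equal(d_open, d_closed)) || d_open == d_closed)
    stopf("session has no dynamic range (d_open == d_closed)")
  out <- lapply(raw_traces, function(tr)
    eyelid_trace(clip01((d_open - tr$values) / (d_open - d_closed)),
                 tr$sampling_rate, trial_id = tr$trial_id))
  attr(out, "anchors") <- c(open = d_open, closed = d_closed)
  out
}
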