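#' First-order Savitzky-Golay smoothing
#'
#' Thin wrapper around [signal::sgolayfilt()] with polynomial order 1.
#' On interior points a first-order filter with a 3-point window equals
#' the 3-point centered moving average.
#'
#' @param x Numeric vector.
#' @param window Odd window length.
#' @return The smoothed vector, same length as `x`.
#' @export
sgolay_smooth <- function(x, window = 3) {
  if (length(x) < window) return(x)
  signal::sgolayfilt(x, p = 1, n = window)
}

#' Speed-binned average swing trajectories
#'
#' For every complete stride of a paw, extracts the (x, y, z) trajectory
#' of the swing (swing onset to the next stance onset, x relative to the
#' body center), resamples it to 100 equidistant points with linear
#' interpolation, bins strides by their forward speed (stride length over
#' stride duration), averages the resampled trajectories within each
#' bin, and smooths the averages with a first-order, 3-point
#' Savitzky-Golay filter. Empty bins are missing entries, not zeros.
#'
#' @param strides A [segment_strides()] result for the paw.
#' @param tracks The [paw_tracks()] object.
#' @param speed_bins Bin edges for stride speed, m/s; `NULL` for a single
#'   bin covering everything.
#' @param n_points Number of resampled points per swing.
#' @return A list, one entry per non-empty bin (named
#'   `"lo-hi"` in m/s), each an `n_points x 3` matrix with columns
#'   `x`, `y`, `z` (mm) and attribute `"n_swings"`.
#' @export
align_trajectories <- function(strides, tracks, speed_bins = NULL,
                               n_points = 100) {
  st <- strides$stance_onset
  sw <- strides$swing_onset
  if (length(st) < 2L) stopf("need at least one complete stride")
  lp <- limb_params(strides, tracks)
  if (is.null(speed_bins))
    speed_bins <- range(lp$stride_length_mm / 1000 / lp$stride_duration_s) +
      c(-1e-9, 1e-9)
  x_rel <- tracks$paws[[strides$paw]]$x - tracks$body_x
  y <- tracks$paws[[strides$paw]]$y
  z <- tracks$paws[[strides$paw]]$z
  swings <- list()
  speeds <- numeric(0)
  for (i in seq_len(nrow(lp))) {
    t0 <- lp$stance_onset_s[i]
    t1 <- st[st > t0][1]
    lift <- sw[sw > t0 & sw < t1][1]
    idx <- time_index(tracks, lift):time_index(tracks, t1)
    if (length(idx) < 2L) next
    u <- seq(tracks$time[idx[1]], tracks$time[idx[length(idx)]],
             length.out = n_points)
    traj <- cbind(
      x = approx(tracks$time[idx], x_rel[idx], xout = u)$y,
      y = approx(tracks$time[idx], y[idx], xout = u)$y,
      z = approx(tracks$time[idx], z[idx], xout = u)$y)
    swings[[length(swings) + 1L]] <- traj
    speeds <- c(speeds,
                lp$stride_length_mm[i] / 1000 / lp$stride_duration_s[i])
  }
  if (!length(swings)) stopf("no swing trajectories found")
  bin <- cut(speeds, speed_bins, right = FALSE, include.lowest = TRUE,
             labels = FALSE)
  out <- list()
  for (b in sort(unique(bin[!is.na(bin)]))) {
    sel <- which(bin == b)
    avg <- Reduce(`+`, swings[sel]) / length(sel)
    sm <- apply(avg, 2, sgolay_smooth)
    colnames(sm) <- c("x", "y", "z")
    attr(sm, "n_swings") <- length(sel)
    out[[sprintf("%g-%g", speed_bins[b], speed_bins[b + 1])]] <- sm
  }
  out
}
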