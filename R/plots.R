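#' Plot per-session learning curves
#'
#' @param curves Output of [learning_curve()], optionally row-bound
#'   across mice with a `group` column.
#' @param what `"pct_cr"` or `"mean_amplitude"`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the session-by-group matrix plotted.
#' @export
plot_learning_curve <- function(curves, what = c("pct_cr", "mean_amplitude"),
                                ...) {
  what <- match.arg(what)
  if (is.null(curves$group)) curves$group <- "all"
  agg <- aggregate(curves[[what]],
                   by = list(session = curves$session, group = curves$group),
                   FUN = mean)
  m <- tapply(agg$x, list(agg$session, agg$group), identity)
  graphics::matplot(as.integer(rownames(m)), m, type = "b", pch = 16,
                    xlab = "Session",
                    ylab = if (what == "pct_cr") "% CR" else
                      "Mean CR amplitude", ...)
  graphics::legend("topleft", legend = colnames(m), bty = "n",
                   col = seq_len(ncol(m)), lty = seq_len(ncol(m)))
  invisible(m)
}

#' Plot a split-belt adaptation series
#'
#' Per-trial asymmetry with the split period shaded and session breaks
#' marked.
#'
#' @param series An `adaptation_series`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `series`.
#' @export
plot_adaptation <- function(series, ...) {
  graphics::plot(series$trial, series$asymmetry, type = "n",
                 xlab = "Trial", ylab = "Asymmetry (fast - slow)", ...)
  split_tr <- range(series$trial[series$phase == "split"])
  graphics::rect(split_tr[1] - 0.5, graphics::par("usr")[3],
                 split_tr[2] + 0.5, graphics::par("usr")[4],
                 col = "grey90", border = NA)
  breaks <- series$trial[c(FALSE, diff(series$session) > 0)] - 0.5
  graphics::abline(v = breaks, col = "grey70")
  graphics::abline(h = 0, lty = 2)
  graphics::lines(series$trial, series$asymmetry, type = "b", pch = 16)
  invisible(series)
}
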