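#' Trial-level mixed model of CR amplitude on walking speed
#'
#' Fits a linear mixed model of trial CR amplitude on trial walking speed
#' with random slopes and intercepts per mouse,
#' `amplitude ~ speed + (1 + speed | mouse_id)`, and reports the fixed
#' slope with an F test using the Satterthwaite degrees-of-freedom
#' correction. With a single mouse the model is unidentifiable and the
#' fit falls back to ordinary least squares, with a warning.
#'
#' @param trials Data frame with `mouse_id`, `speed`, `amplitude`.
#' @param conf_level Confidence level for the slope interval.
#' @return An object of class `"speed_amplitude_fit"`: `slope`, `se`,
#'   `df` (denominator, Satterthwaite), `F`, `p`, `ci`, `method`
#'   (`"lmer"` or `"ols"`), `n_mice`, `n_trials`, and the underlying
#'   `model`.
#' @export
fit_speed_amplitude_mixed <- function(trials, conf_level = 0.95) {
  need <- c("mouse_id", "speed", "amplitude")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  if (var(trials$speed) < .Machine$double.eps)
    stopf("speed is constant; the slope is not identifiable")
  n_mice <- length(unique(trials$mouse_id))
  if (n_mice < 2L) {
    warnf("single mouse: falling back to ordinary least squares")
    m <- lm(amplitude ~ speed, data = trials)
    cf <- summary(m)$coefficients["speed", ]
    df <- m$df.residual
    est <- cf[["Estimate"]]; se <- cf[["Std. Error"]]
    fit <- list(slope = est, se = se, df = df, F = cf[["t value"]]^2,
                p = cf[["Pr(>|t|)"]], method = "ols", model = m)
  } else {
    if (min(table(trials$mouse_id)) < 2L)
      stopf("each mouse needs >= 2 trials for the mixed fit")
    ctrl <- lme4::lmerControl(
      calc.derivs = FALSE,
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
    m <- suppressMessages(lmerTest::lmer(
      amplitude ~ speed + (1 + speed | mouse_id), data = trials,
      control = ctrl))
    cf <- coef(summary(m))["speed", ]
    est <- cf[["Estimate"]]; se <- cf[["Std. Error"]]; df <- cf[["df"]]
    fit <- list(slope = est, se = se, df = df, F = cf[["t value"]]^2,
                p = cf[["Pr(>|t|)"]], method = "lmer", model = m)
  }
  alpha <- 1 - conf_level
  fit$ci <- est + c(-1, 1) * qt(1 - alpha / 2, df) * se
  fit$conf_level <- conf_level
  fit$n_mice <- n_mice
  fit$n_trials <- nrow(trials)
  class(fit) <- "speed_amplitude_fit"
  fit
}

#' @export
print.speed_amplitude_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<speed_amplitude_fit> (%s, %d mice, %d trials)\n",
           "  slope %.4f closure/(m/s)  [%.0f%% CI %.4f, %.4f]\n",
           "  F(1, %.1f) = %.2f, p = %.3g\n"),
    x$method, x$n_mice, x$n_trials, x$slope, 100 * x$conf_level,
    x$ci[1], x$ci[2], x$df, x$F, x$p))
  invisible(x)
}

#' Robust fit of learning onset on locomotor activity
#'
#' Robust (bisquare-weighted iteratively reweighted least squares) linear
#' regression of per-animal learning-onset session on per-animal mean
#' walking distance, with an optional activity split of the animals at a
#' distance threshold (150 m/session by default). Animals without a
#' defined onset are dropped. If the remaining points are fit exactly by
#' ordinary least squares (zero residual scale, where the IRLS weights
#' are undefined), that exact fit is returned.
#'
#' @param onset Per-animal onset sessions (may contain `NA`).
#' @param distance Per-animal mean distance per session, metres.
#' @param activity_split Distance threshold dividing low- from
#'   high-activity animals, m/session.
#' @param maxit,acc IRLS iteration cap and convergence tolerance.
#' @return An object of class `"robust_onset_fit"`: `slope`, `intercept`,
#'   `se`, `t`, `p` (t approximation with n - 2 df), `n`, and `groups`
#'   (data frame with the activity split).
#' @export
robust_onset_vs_activity <- function(onset, distance, activity_split = 150,
                                     maxit = 50, acc = 1e-8) {
  if (length(onset) != length(distance)) stopf("length mismatch")
  ok <- is.finite(onset) & is.finite(distance)
  if (sum(ok) < 3L) stopf("need >= 3 animals with a defined onset")
  x <- distance[ok]; y <- onset[ok]
  ls <- lm(y ~ x)
  if (sd(residuals(ls)) < 1e-10 * max(1, sd(y))) {
    cf <- coef(ls)
    slope <- unname(cf[2]); intercept <- unname(cf[1])
    se <- 0; tval <- Inf; p <- 0
    if (abs(slope) < 1e-12) { tval <- 0; p <- 1 }
  } else {
    m <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = maxit,
                   acc = acc)
    cf <- summary(m)$coefficients
    slope <- cf["x", "Value"]; intercept <- cf["(Intercept)", "Value"]
    se <- cf["x", "Std. Error"]
    tval <- cf["x", "t value"]
    p <- 2 * pt(-abs(tval), df = sum(ok) - 2)
  }
  structure(list(
    slope = slope, intercept = intercept, se = se, t = tval, p = p,
    n = sum(ok),
    groups = data.frame(onset = onset, distance = distance,
                        high_activity = distance >= activity_split)),
    class = "robust_onset_fit")
}

#' @export
print.robust_onset_fit <- function(x, ...) {
  cat(sprintf(
    "<robust_onset_fit> slope %.4f sessions/m (t = %.2f, p = %.3g, n = %d)\n",
    x$slope, x$t, x$p, x$n))
  invisible(x)
}
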