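#' Define a split-belt adaptation protocol
#'
#' A protocol is an ordered table of one-minute treadmill trials, each
#' labeled baseline (tied belts), split (unequal belt speeds) or washout
#' (tied again). Phases must appear in that order; session breaks within a
#' phase are allowed.
#'
#' @param phase Character vector of `"baseline"`, `"split"`, `"washout"`
#'   labels, one per trial, in order.
#' @param speed_slow,speed_fast Belt speeds in m/s per trial (equal on tied
#'   trials; `speed_fast > speed_slow` on split trials). Scalars are
#'   recycled within a phase.
#' @param session 1-based session index per trial.
#' @param duration_s Trial duration, seconds.
#' @return A data frame of class `"splitbelt_protocol"` with columns
#'   `trial`, `session`, `phase`, `speed_slow`, `speed_fast`, `duration_s`.
#' @examples
#' p <- splitbelt_protocol_single()
#' nrow(p)            # 18 trials: 2 tied + 8 split + 8 tied
#' @export
splitbelt_protocol <- function(phase, speed_slow, speed_fast,
                               session = 1L, duration_s = 60) {
  n <- length(phase)
  if (n == 0L) stopf("empty protocol")
  proto <- data.frame(
    trial = seq_len(n),
    session = as.integer(rep_len(session, n)),
    phase = as.character(phase),
    speed_slow = rep_len(as.numeric(speed_slow), n),
    speed_fast = rep_len(as.numeric(speed_fast), n),
    duration_s = rep_len(as.numeric(duration_s), n),
    stringsAsFactors = FALSE)
  class(proto) <- c("splitbelt_protocol", "data.frame")
  validate_protocol(proto)
}

validate_protocol <- function(proto) {
  if (!is.data.frame(proto) || nrow(proto) == 0L)
    stopf("empty protocol")
  need <- c("trial", "session", "phase", "speed_slow", "speed_fast",
            "duration_s")
  miss <- setdiff(need, names(proto))
  if (length(miss)) stopf("protocol missing column(s): %s",
                          paste(miss, collapse = ", "))
  ok_phase <- c("baseline", "split", "washout")
  if (!all(proto$phase %in% ok_phase))
    stopf("phase labels must be one of: %s", paste(ok_phase, collapse = ", "))
  # phases must be contiguous and ordered baseline -> split -> washout
  r <- rle(proto$phase)$values
  if (any(duplicated(r)) ||
      !identical(r, ok_phase[ok_phase %in% r]))
    stopf("phases must appear in order baseline -> split -> washout")
  if (any(proto$speed_slow <= 0) || any(proto$speed_fast <= 0))
    stopf("belt speeds must be positive")
  split <- proto$phase == "split"
  if (any(split) && any(proto$speed_fast[split] <= proto$speed_slow[split]))
    stopf("split trials require speed_fast > speed_slow")
  tied <- !split
  if (any(proto$speed_fast[tied] != proto$speed_slow[tied]))
    stopf("tied (baseline/washout) trials require equal belt speeds")
  if (is.unsorted(proto$session)) stopf("sessions must be non-decreasing")
  class(proto) <- unique(c("splitbelt_protocol", class(proto)))
  proto
}

#' @rdname splitbelt_protocol
#' @details `splitbelt_protocol_single()` is the built-in single-session
#'   protocol: two tied, eight split and eight tied one-minute trials with
#'   split speeds 0.175 m/s (slow) and 0.375 m/s (fast), a 2.14:1 ratio.
#'   The tied-trial speed defaults to the midpoint, 0.275 m/s.
#' @param tied_speed Belt speed on tied trials, m/s.
#' @export
splitbelt_protocol_single <- function(tied_speed = 0.275) {
  splitbelt_protocol(
    phase = rep(c("baseline", "split", "washout"), c(2, 8, 8)),
    speed_slow = rep(c(tied_speed, 0.175, tied_speed), c(2, 8, 8)),
    speed_fast = rep(c(tied_speed, 0.375, tied_speed), c(2, 8, 8)),
    session = 1L)
}

#' @rdname splitbelt_protocol
#' @details `splitbelt_protocol_multi()` is the built-in five-session
#'   protocol of 10 trials per day (session 1: three tied, seven split;
#'   sessions 2-3: all split; session 4: three split, seven tied;
#'   session 5: all tied) with tied speed 0.2 m/s and split speeds
#'   0.125/0.275 m/s.
#' @export
splitbelt_protocol_multi <- function() {
  phase <- c(rep("baseline", 3), rep("split", 7),   # session 1
             rep("split", 20),                      # sessions 2-3
             rep("split", 3), rep("washout", 7),    # session 4
             rep("washout", 10))                    # session 5
  split <- phase == "split"
  splitbelt_protocol(
    phase = phase,
    speed_slow = ifelse(split, 0.125, 0.2),
    speed_fast = ifelse(split, 0.275, 0.2),
    session = rep(1:5, each = 10))
}

#' Read or write a split-belt protocol as YAML
#'
#' The YAML layout is a list of trial blocks with fields `phase`,
#' `speed_slow`, `speed_fast`, `session` and `duration_s`.
#'
#' @param path File path.
#' @return `read_protocol()` returns a validated protocol data frame.
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$trials)) stopf("protocol YAML must contain a `trials` list")
  tr <- do.call(rbind, lapply(y$trials, function(t)
    data.frame(session = as.integer(t$session %||% 1L),
               phase = t$phase,
               speed_slow = t$speed_slow, speed_fast = t$speed_fast,
               duration_s = t$duration_s %||% 60)))
  tr$trial <- seq_len(nrow(tr))
  validate_protocol(tr[, c("trial", "session", "phase", "speed_slow",
                           "speed_fast", "duration_s")])
}

#' @rdname read_protocol
#' @param protocol A protocol data frame.
#' @export
write_protocol <- function(protocol, path) {
  protocol <- validate_protocol(protocol)
  y <- list(trials = lapply(seq_len(nrow(protocol)), function(i)
    list(session = protocol$session[i], phase = protocol$phase[i],
         speed_slow = protocol$speed_slow[i],
         speed_fast = protocol$speed_fast[i],
         duration_s = protocol$duration_s[i])))
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
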