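# Trial-table CSV schema shared by the generators and the analyses.
TRIAL_TABLE_COLUMNS <- c("mouse_id", "group", "session", "trial_index",
                         "trial_type", "cs_onset_s", "isi_s", "us_present",
                         "us_duration_s", "trace_ref", "wheel_ref")

#' Read and validate a trial table
#'
#' The trial-table CSV has one row per trial with columns `mouse_id`,
#' `group`, `session`, `trial_index`, `trial_type` (`paired`/`cs_only`),
#' `cs_onset_s`, `isi_s`, `us_present`, `us_duration_s`, `trace_ref`,
#' `wheel_ref` (extra columns pass through). Sessions and trial indices
#' are 1-based; times are in seconds.
#'
#' @param path CSV file path.
#' @param trace_dir Optional directory; when given, every `trace_ref`
#'   must resolve to `<trace_dir>/<trace_ref>.csv`.
#' @return The validated trial table (data frame).
#' @export
read_trial_table <- function(path, trace_dir = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  validate_trial_table(read.csv(path, stringsAsFactors = FALSE), trace_dir)
}

#' @rdname read_trial_table
#' @param trials Trial table data frame.
#' @export
validate_trial_table <- function(trials, trace_dir = NULL) {
  miss <- setdiff(TRIAL_TABLE_COLUMNS, names(trials))
  if (length(miss))
    stopf("trial table is missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(trials$trial_type %in% c("paired", "cs_only")))
    stopf("trial_type must be 'paired' or 'cs_only'")
  if (!is.numeric(trials$isi_s) || any(trials$isi_s <= 0))
    stopf("isi_s must be positive")
  if (any(trials$cs_onset_s < 0)) stopf("cs_onset_s must be >= 0")
  if (any(trials$session < 1) || any(trials$trial_index < 1))
    stopf("sessions and trial indices are 1-based")
  key <- paste(trials$mouse_id, trials$session, trials$trial_index)
  if (anyDuplicated(key))
    stopf("duplicate trial key(s): %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!is.null(trace_dir)) {
    refs <- unique(trials$trace_ref)
    missing_refs <- refs[!file.exists(file.path(trace_dir,
                                                paste0(refs, ".csv")))]
    if (length(missing_refs))
      stopf("unresolved trace_ref(s): %s",
            paste(missing_refs, collapse = ", "))
  }
  trials
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Write and read per-trial eyelid traces as CSV
#'
#' One CSV per trial with columns `frame_index` (0-based), `time_s` and
#' `closure` (or `raw_px` for raw traces).
#'
#' @param trace An [eyelid_trace()] or [raw_eyelid_trace()].
#' @param path CSV file path.
#' @export
write_trace_csv <- function(trace, path) {
  value_col <- if (inherits(trace, "eyelid_trace")) "closure" else "raw_px"
  d <- data.frame(frame_index = seq_along(trace$values) - 1L,
                  time_s = trace_times(trace))
  d[[value_col]] <- trace$values
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param sampling_rate Sampling rate override; by default inferred from
#'   the `time_s` column.
#' @param trial_id Optional trial identifier.
#' @export
read_trace_csv <- function(path, sampling_rate = NULL, trial_id = NULL) {
  d <- read.csv(path)
  if (is.null(sampling_rate))
    sampling_rate <- 1 / median(diff(d$time_s))
  if ("closure" %in% names(d))
    eyelid_trace(d$closure, sampling_rate, trial_id)
  else if ("raw_px" %in% names(d))
    raw_eyelid_trace(d$raw_px, sampling_rate, trial_id)
  else stopf("trace CSV needs a `closure` or `raw_px` column")
}

#' Write and read paw tracks as wide CSV
#'
#' Columns: `time_s`, then `x`/`y`/`z` per paw (`FR_x`, `FR_y`, ...) and
#' `body_x`, all in mm.
#'
#' @param tracks A [paw_tracks()] object.
#' @param path CSV file path.
#' @export
write_paw_tracks <- function(tracks, path) {
  d <- data.frame(time_s = tracks$time)
  for (p in PAW_NAMES) for (ax in c("x", "y", "z"))
    d[[paste0(p, "_", ax)]] <- tracks$paws[[p]][[ax]]
  d$body_x <- tracks$body_x
  write.csv(d, path, row.names = FALSE)
  meta <- list(frame_rate = tracks$frame_rate, context = tracks$context,
               belt_speed = as.list(tracks$belt_speed))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_paw_tracks
#' @export
read_paw_tracks <- function(path) {
  d <- read.csv(path)
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path)) stopf("missing metadata file %s", meta_path)
  meta <- yaml::read_yaml(meta_path)
  paws <- lapply(setNames(nm = PAW_NAMES), function(p)
    list(x = d[[paste0(p, "_x")]], y = d[[paste0(p, "_y")]],
         z = d[[paste0(p, "_z")]]))
  paw_tracks(d$time_s, paws, d$body_x, meta$frame_rate, meta$context,
             unlist(meta$belt_speed))
}

#' Run configuration with the assay's standard thresholds
#'
#' Collects the analysis thresholds in one validated list. Defaults are
#' the assay's stated values: CR threshold 0.1 normalized closure;
#' stationary below 0.05 m/s mean speed; onset when the session mean CR
#' amplitude exceeds 0.1.
#'
#' @param cr_threshold CR amplitude threshold, normalized closure.
#' @param stationary_threshold Stationary cutoff on trial mean speed, m/s.
#' @param walking_threshold Walking cutoff for fraction of time walking,
#'   m/s.
#' @param contact_height Paw ground-contact threshold on z, mm.
#' @param onset_threshold Learning-onset threshold on session mean CR
#'   amplitude.
#' @param speed_bin_width Width of speed bins, m/s.
#' @param seed Integer seed for any simulation steps.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(cr_threshold = 0.1, stationary_threshold = 0.05,
                       walking_threshold = 0.01, contact_height = 1,
                       onset_threshold = 0.1, speed_bin_width = 0.05,
                       seed = 1L) {
  assert_scalar_num(cr_threshold, "cr_threshold", 0, 1)
  assert_scalar_num(stationary_threshold, "stationary_threshold", 0)
  assert_scalar_num(walking_threshold, "walking_threshold", 0)
  assert_scalar_num(contact_height, "contact_height", 0, strict_lower = TRUE)
  assert_scalar_num(onset_threshold, "onset_threshold", 0)
  assert_scalar_num(speed_bin_width, "speed_bin_width", 0,
                    strict_lower = TRUE)
  structure(list(cr_threshold = cr_threshold,
                 stationary_threshold = stationary_threshold,
                 walking_threshold = walking_threshold,
                 contact_height = contact_height,
                 onset_threshold = onset_threshold,
                 speed_bin_width = speed_bin_width,
                 seed = assert_seed(seed)), class = "run_config")
}
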