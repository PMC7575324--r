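#' Run a pipeline step end to end
#'
#' Orchestrates the package's analyses over files on disk. Subcommands:
#' \describe{
#'   \item{simulate}{generate an eyeblink cohort, a gait session and a
#'     split-belt series from the seed and write them under `out_dir`.}
#'   \item{extract}{convert a directory of eye-frame images (PNG/TIFF,
#'     `frames_dir` in `config`) into a raw eyelid-distance trace CSV.}
#'   \item{eyeblink}{read `trials.csv`, classify CRs, and write
#'     per-session learning curves (`learning_curves.csv`) and per-animal
#'     onset sessions (`onsets.csv`).}
#'   \item{gait}{read a paw-track CSV (`tracks.csv`) and write per-stride
#'     limb parameters (`gait_params.csv`).}
#'   \item{splitbelt}{read an adaptation series (`splitbelt_series.csv`)
#'     and write its phase metrics (`phase_metrics.csv`).}
#'   \item{report}{summarize all outputs in `out_dir` into `report.txt`;
#'     an empty directory is an error and writes nothing.}
#' }
#' Every invocation writes `run_manifest.json` recording the subcommand,
#' seed, configuration hash, package version and output files, so any
#' output is regenerable from the manifest alone.
#'
#' @param subcommand One of `simulate`, `extract`, `eyeblink`, `gait`,
#'   `splitbelt`, `report`.
#' @param config A [run_config()] (or list of overrides); may carry
#'   additional fields used by specific subcommands (`eyeblink_config`,
#'   `gait_config`, `splitbelt_config`, `frames_dir`, `sampling_rate`,
#'   `traces`).
#' @param out_dir Output (and, for analysis steps, input) directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(subcommand, config = run_config(),
                         out_dir = ".") {
  subcommands <- c("simulate", "extract", "eyeblink", "gait", "splitbelt",
                   "report")
  if (!is.character(subcommand) || length(subcommand) != 1L ||
      !subcommand %in% subcommands)
    stopf("unknown subcommand; use one of: %s",
          paste(subcommands, collapse = ", "))
  if (!inherits(config, "run_config")) {
    base <- run_config()
    extra <- config
    config <- utils::modifyList(base, extra)
    class(config) <- "run_config"
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- switch(subcommand,
    simulate = pipeline_simulate(config, out_dir),
    extract = pipeline_extract(config, out_dir),
    eyeblink = pipeline_eyeblink(config, out_dir),
    gait = pipeline_gait(config, out_dir),
    splitbelt = pipeline_splitbelt(config, out_dir),
    report = pipeline_report(config, out_dir))
  manifest <- list(
    subcommand = subcommand, seed = config$seed,
    config = config[order(names(config))],
    config_hash = config_hash(config),
    package_version = as.character(packageVersion("locolearn")),
    files = sort(basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- config[order(names(config))]
  cfg <- cfg[!vapply(cfg, is.object, logical(1))]
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

pipeline_simulate <- function(config, out_dir) {
  eb_cfg <- config$eyeblink_config %||%
    eyeblink_sim_config(n_mice_per_group = 2, n_sessions = 4,
                        trials_per_session = c(paired = 20, cs_only = 2),
                        acquisition_gain = 5e-3, seed = config$seed)
  cohort <- gen_eyeblink_cohort(eb_cfg, traces = isTRUE(config$traces))
  f1 <- file.path(out_dir, "trials.csv")
  write_trial_table(cohort$trials, f1)
  gait_cfg <- config$gait_config %||%
    gait_sim_config(duration = 3, seed = config$seed)
  f2 <- file.path(out_dir, "tracks.csv")
  write_paw_tracks(gen_gait_session(gait_cfg), f2)
  sb_cfg <- config$splitbelt_config %||%
    splitbelt_sim_config(seed = config$seed)
  f3 <- file.path(out_dir, "splitbelt_series.csv")
  write.csv(gen_splitbelt_series(sb_cfg), f3, row.names = FALSE)
  c(f1, f2, f3)
}

pipeline_extract <- function(config, out_dir) {
  if (is.null(config$frames_dir)) stopf("extract needs `frames_dir`")
  paths <- sort(list.files(config$frames_dir, full.names = TRUE,
                           pattern = "\\.(png|tif|tiff)$"))
  if (!length(paths)) stopf("no PNG/TIFF frames in %s", config$frames_dir)
  frames <- lapply(paths, function(p) {
    img <- EBImage::imageData(EBImage::readImage(p))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    t(img)  # readImage is column-major x,y; analysis uses row x col
  })
  rate <- config$sampling_rate %||% 900
  tr <- extract_eyelid_trace(frames, sampling_rate = rate)
  f <- file.path(out_dir, "eyelid_raw_trace.csv")
  write_trace_csv(tr, f)
  f
}

pipeline_eyeblink <- function(config, out_dir) {
  trials <- read_trial_table(file.path(out_dir, "trials.csv"))
  classified <- classify_cr_trials(list(trials = trials),
                                   threshold = config$cr_threshold)
  curves <- do.call(rbind, lapply(split(classified, classified$mouse_id),
                                  function(d) {
    lc <- learning_curve(d)
    lc$mouse_id <- d$mouse_id[1]
    lc$group <- d$group[1]
    lc
  }))
  rownames(curves) <- NULL
  f1 <- file.path(out_dir, "learning_curves.csv")
  write.csv(curves, f1, row.names = FALSE)
  onsets <- do.call(rbind, lapply(split(curves, curves$mouse_id),
                                  function(d) data.frame(
    mouse_id = d$mouse_id[1], group = d$group[1],
    onset_session = learning_onset(d$mean_amplitude[order(d$session)],
                                   threshold = config$onset_threshold))))
  rownames(onsets) <- NULL
  f2 <- file.path(out_dir, "onsets.csv")
  write.csv(onsets, f2, row.names = FALSE)
  c(f1, f2)
}

pipeline_gait <- function(config, out_dir) {
  tracks <- read_paw_tracks(file.path(out_dir, "tracks.csv"))
  params <- do.call(rbind, lapply(PAW_NAMES, function(p)
    limb_params(segment_strides(tracks, p), tracks)))
  f <- file.path(out_dir, "gait_params.csv")
  write.csv(params, f, row.names = FALSE)
  f
}

pipeline_splitbelt <- function(config, out_dir) {
  series <- read.csv(file.path(out_dir, "splitbelt_series.csv"))
  pm <- phase_metrics(series)
  f <- file.path(out_dir, "phase_metrics.csv")
  write.csv(data.frame(initial_error = pm$initial_error,
                       change_over_split = pm$change_over_split,
                       aftereffect = pm$aftereffect), f, row.names = FALSE)
  f
}

pipeline_report <- function(config, out_dir) {
  outputs <- setdiff(list.files(out_dir, pattern = "\\.csv$"),
                     "report.txt")
  if (!length(outputs))
    stopf("no pipeline outputs in %s; nothing to report", out_dir)
  lines <- c("locolearn pipeline report", strrep("=", 25), "")
  for (f in outputs) {
    d <- read.csv(file.path(out_dir, f))
    lines <- c(lines, sprintf("%s: %d rows x %d cols (%s)", f, nrow(d),
                              ncol(d), paste(names(d), collapse = ", ")))
  }
  f <- file.path(out_dir, "report.txt")
  writeLines(lines, f)
  f
}
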