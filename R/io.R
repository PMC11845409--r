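#' Recording bundle
#'
#' Groups the on-disk artifacts of one participant x condition session:
#' tracking TSV, EEG container and events TSV.
#'
#' @param tracking_path,eeg_path,events_path File paths.
#' @param participant_id Participant label.
#' @param condition One of "static", "slow", "natural".
#' @param tracking_rate,eeg_rate Sampling rates (Hz).
#' @param check_exists Verify the files exist now.
#' @return Object of class `recording_bundle`.
#' @export
recording_bundle <- function(tracking_path, eeg_path, events_path,
                             participant_id, condition,
                             tracking_rate = 90, eeg_rate = 300,
                             check_exists = TRUE) {
  condition <- match.arg(condition, c("static", "slow", "natural"))
  assert_that(tracking_rate > 0 && eeg_rate > 0,
              "sampling rates must be positive")
  if (check_exists) {
    for (p in c(tracking_path, eeg_path, events_path))
      if (!file.exists(p)) stop("file not found: ", p)
  }
  structure(list(tracking_path = tracking_path, eeg_path = eeg_path,
                 events_path = events_path, participant_id = participant_id,
                 condition = condition, tracking_rate = tracking_rate,
                 eeg_rate = eeg_rate),
            class = "recording_bundle")
}

tracking_columns <- function() {
  c("time_s", "head_x", "head_y", "head_z",
    "gaze_origin_x", "gaze_origin_y", "gaze_origin_z",
    "gaze_dir_x", "gaze_dir_y", "gaze_dir_z", "trial_id")
}

#' Read a tracking stream
#'
#' Reads the TSV/CSV tracking schema (time_s, head_x/y/z, gaze_origin_x/y/z,
#' gaze_dir_x/y/z, trial_id), renormalizes gaze directions to unit length and
#' flags sampling gaps longer than two samples as dropout intervals.
#'
#' @param path TSV or CSV file.
#' @param rate Expected sampling rate (Hz), used for gap detection.
#' @return A `gh_recording`: data.table plus `rate` and `dropouts`
#'   attributes (`dropouts`: start_s, end_s, n_missing).
#' @export
read_tracking <- function(path, rate = 90) {
  dt <- data.table::fread(path)
  miss <- setdiff(tracking_columns(), names(dt))
  if (length(miss))
    stop("tracking format error: missing column(s) ", paste(miss, collapse = ", "))
  if (any(diff(dt$time_s) <= 0))
    stop("tracking format error: time_s is not strictly increasing")
  nrm <- sqrt(dt$gaze_dir_x^2 + dt$gaze_dir_y^2 + dt$gaze_dir_z^2)
  bad <- which(nrm == 0)
  if (length(bad))
    stop("tracking format error: zero-norm gaze_dir at row(s) ",
         paste(head(bad, 10), collapse = ", "))
  dt[, c("gaze_dir_x", "gaze_dir_y", "gaze_dir_z") :=
       list(gaze_dir_x / nrm, gaze_dir_y / nrm, gaze_dir_z / nrm)]
  gaps <- diff(dt$time_s)
  gap_idx <- which(gaps > 2.5 / rate)
  dropouts <- data.frame(
    start_s = dt$time_s[gap_idx], end_s = dt$time_s[gap_idx + 1L],
    n_missing = round(gaps[gap_idx] * rate) - 1L)
  structure(dt, class = c("gh_recording", class(dt)),
            rate = rate, dropouts = dropouts)
}

new_eeg_recording <- function(data, channels, rate, time, triggers,
                              bad_channels = character(0)) {
  stopifnot(nrow(data) == length(channels), !anyDuplicated(channels))
  structure(list(data = data, channels = channels, rate = rate, time = time,
                 triggers = triggers, bad_channels = bad_channels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("eeg_recording:", length(x$channels), "channels x",
      ncol(x$data), "samples @", x$rate, "Hz;",
      nrow(x$triggers), "triggers;",
      length(x$bad_channels), "bad channel(s)\n")
  invisible(x)
}

#' Write / read the EEG text container
#'
#' Plain-text interchange for multichannel EEG: a wide TSV (`time_s` plus one
#' column per channel, channels in canonical order with A1/A2 last) and a
#' sibling `<stem>_triggers.tsv` with columns onset_s, code.
#'
#' @param rec An `eeg_recording`.
#' @param path Path of the data TSV.
#' @return `write_eeg`: the path, invisibly. `read_eeg`: an `eeg_recording`.
#' @export
write_eeg <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- data.table::data.table(time_s = rec$time)
  for (i in seq_along(rec$channels)) df[[rec$channels[i]]] <- rec$data[i, ]
  data.table::fwrite(df, path, sep = "\t")
  data.table::fwrite(rec$triggers, trigger_path(path), sep = "\t")
  invisible(path)
}

trigger_path <- function(path) sub("\\.tsv$", "_triggers.tsv", path)

#' @rdname write_eeg
#' @export
read_eeg <- function(path) {
  dt <- data.table::fread(path)
  if (!"time_s" %in% names(dt)) stop("EEG format error: no time_s column")
  chans <- setdiff(names(dt), "time_s")
  for (ref in c("A1", "A2"))
    if (!ref %in% chans)
      stop("EEG format error: reference channel ", ref,
           " missing; re-referencing impossible")
  canonical <- intersect(eeg_channels(), chans)
  chans <- c(canonical, setdiff(chans, canonical))
  time <- dt$time_s
  rate <- round(1 / median(diff(time)))
  data <- t(as.matrix(dt[, chans, with = FALSE]))
  tp <- trigger_path(path)
  triggers <- if (file.exists(tp)) as.data.frame(data.table::fread(tp)) else
    data.frame(onset_s = numeric(0), code = integer(0))
  new_eeg_recording(data = data, channels = chans, rate = rate, time = time,
                    triggers = triggers)
}

#' Read a BIDS-style events table
#'
#' @param path TSV with columns onset, duration, trial_type (extra columns
#'   preserved).
#' @return data.frame of events.
#' @export
read_events <- function(path) {
  ev <- as.data.frame(data.table::fread(path))
  miss <- setdiff(c("onset", "duration", "trial_type"), names(ev))
  if (length(miss))
    stop("events format error: missing column(s) ", paste(miss, collapse = ", "))
  ev
}

#' Analysis configuration
#'
#' All tunables of the pipeline with defaults equal to the published
#' procedure: velocity-threshold multiplier 6, 2-sample (22 ms) minimum
#' saccade duration, 5-sample velocity smoothing, 0.8-m blink criterion,
#' 40 phase bins, 0.2-10 cycles-per-stride scan in 0.2 steps, 1000
#' permutations for the Fourier null, 0.1-40 Hz EEG band-pass, 3-40 Hz
#' 50-step Morlet grid with 600-100 ms FWHM, cluster-forming p 0.01 with
#' 2000 permutations. Every stochastic stage draws from `seed`.
#'
#' @param ... Overrides of the defaults (named, nested lists merged shallowly
#'   per section).
#' @param seed Top-level seed.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(..., seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    saccade = list(lambda_mult = 6, min_samples = 2L, smooth_window = 5L,
                   blink_jump = 0.8),
    gait = list(lowpass_hz = 6, min_separation_s = 0.35, prominence_frac = 0.25,
                step_bounds_s = c(0.4, 1.2), stride_convention = "one-step-overlap",
                max_dropout_s = 0.25, max_bad_step_frac = 0.2),
    cyclic = list(n_bins = 40L, freq_grid = seq(0.2, 10, by = 0.2),
                  n_perm = 1000L, band = c(1.5, 2.5),
                  prevalence_alpha = 0.05, prevalence_beta = 1),
    eeg = list(bandpass_hz = c(0.1, 40), tf_freqs = c(3, 40), tf_n = 50L,
               fwhm_ms = c(600, 100), gait_grid = c(-30, 130, 0.5),
               epoch_pad_s = 0.6, saccade_window_s = c(-0.6, 1.1)),
    cluster = list(p_thresh = 0.01, n_perm = 2000L)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else cfg[[nm]] <- ov[[nm]]
  }
  validate_config(structure(cfg, class = "analysis_config"))
}

validate_config <- function(cfg) {
  assert_that(cfg$cyclic$n_perm >= 1, "permutations must be positive")
  assert_that(cfg$cluster$n_perm >= 1, "permutations must be positive")
  assert_that(cfg$saccade$smooth_window %% 2L == 1L,
              "smooth_window must be odd")
  assert_that(length(cfg$cyclic$freq_grid) > 0, "empty frequency grid")
  cfg
}

#' @rdname analysis_config
#' @param path JSON path.
#' @param cfg An `analysis_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = 12, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, c(raw[setdiff(names(raw), "seed")],
                             list(seed = raw$seed)))
}
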