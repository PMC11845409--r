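# Shared fixtures: all built in code, no files.

# Assemble a gh_recording from a simulated walk + gaze without touching disk.
make_recording <- function(walk, gaze) {
  structure(
    cbind(walk$tracking[, c("time_s", "head_x", "head_y", "head_z")],
          gaze$gaze[, -1], trial_id = walk$tracking$trial_id),
    class = c("gh_recording", "data.table", "data.frame"),
    rate = walk$truth$rate)
}

# A head-only recording (static gaze straight ahead) for gait-only tests.
make_walk_recording <- function(walk) {
  n <- nrow(walk$tracking)
  structure(
    cbind(walk$tracking[, c("time_s", "head_x", "head_y", "head_z")],
          data.table::data.table(
            gaze_origin_x = walk$tracking$head_x,
            gaze_origin_y = walk$tracking$head_y,
            gaze_origin_z = walk$tracking$head_z,
            gaze_dir_x = rep(0, n), gaze_dir_y = rep(0, n),
            gaze_dir_z = rep(1, n)),
          trial_id = walk$tracking$trial_id),
    class = c("gh_recording", "data.table", "data.frame"),
    rate = walk$truth$rate)
}

# Match detected to true event times within tol seconds; returns recall,
# precision.
match_events <- function(detected, truth, tol) {
  if (!length(truth)) return(c(recall = NA, precision = NA))
  rec <- mean(vapply(truth, function(on)
    any(abs(detected - on) <= tol), logical(1)))
  prec <- if (length(detected))
    mean(vapply(detected, function(on)
      any(abs(truth - on) <= tol), logical(1))) else NA
  c(recall = rec, precision = prec)
}

# Small synthetic eeg_recording built directly from a data matrix.
make_eeg <- function(data, rate = 300, triggers = NULL) {
  chans <- rownames(data)
  stridesync:::new_eeg_recording(
    data = data, channels = chans, rate = rate,
    time = (seq_len(ncol(data)) - 1L) / rate,
    triggers = triggers %||% data.frame(onset_s = numeric(0),
                                        code = integer(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
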