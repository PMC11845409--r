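#' Detect blinks from tracking discontinuities
#'
#' A blink is flagged wherever the frame-to-frame displacement on any gaze
#' axis (gaze origin, or gaze direction scaled to a 1-m viewing plane)
#' exceeds `jump` metres. Contiguous flags form intervals; intervals whose
#' +/-100 ms interpolation margins touch are merged.
#'
#' @param rec A `gh_recording` from [read_tracking()].
#' @param jump Displacement criterion (m), default 0.8.
#' @return data.frame with start_s, end_s, interp_start_s, interp_end_s.
#' @export
detect_blinks <- function(rec, jump = 0.8) {
  if (nrow(rec) == 0L) stop("empty recording")
  axes <- rec[, c("gaze_origin_x", "gaze_origin_y", "gaze_origin_z",
                  "gaze_dir_x", "gaze_dir_y", "gaze_dir_z")]
  d <- abs(apply(as.matrix(axes), 2, diff))
  flag <- rowSums(d > jump) > 0         # between samples i and i+1
  bad <- unique(c(which(flag), which(flag) + 1L))
  mask <- rep(FALSE, nrow(rec))
  mask[bad] <- TRUE
  intervals_from_mask(mask, rec$time_s, margin = 0.1)
}

intervals_from_mask <- function(mask, time, margin = 0.1) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start_s = time[starts[keep]], end_s = time[ends[keep]])
  if (nrow(out) > 1L) {
    # merge intervals whose interpolation windows would overlap
    merged <- out[1, , drop = FALSE]
    for (i in 2:nrow(out)) {
      if (out$start_s[i] - merged$end_s[nrow(merged)] <= 2 * margin)
        merged$end_s[nrow(merged)] <- out$end_s[i]
      else merged <- rbind(merged, out[i, ])
    }
    out <- merged
  }
  out$interp_start_s <- out$start_s - margin
  out$interp_end_s <- out$end_s + margin
  rownames(out) <- NULL
  out
}

#' Linearly interpolate gaze over blink windows
#'
#' Replaces samples inside each blink's \[-100 ms, +100 ms\] window by linear
#' interpolation between the window-boundary samples, on all six gaze axes;
#' gaze directions are renormalized afterwards. Head position is untouched.
#' Windows touching the recording edge are clamped with a warning.
#'
#' @param rec A `gh_recording`.
#' @param blinks Output of [detect_blinks()].
#' @return The recording with interpolated gaze and a `blink_mask` attribute
#'   (logical, TRUE inside any interpolation window).
#' @export
interpolate_blinks <- function(rec, blinks) {
  t <- rec$time_s
  n <- length(t)
  mask <- rep(FALSE, n)
  out <- data.table::copy(rec)
  axes <- c("gaze_origin_x", "gaze_origin_y", "gaze_origin_z",
            "gaze_dir_x", "gaze_dir_y", "gaze_dir_z")
  for (i in seq_len(nrow(blinks))) {
    a <- blinks$interp_start_s[i]; b <- blinks$interp_end_s[i]
    if (a < t[1] || b > t[n]) {
      warning("blink window clamped to recording edge")
      a <- max(a, t[1]); b <- min(b, t[n])
    }
    inside <- which(t >= a & t <= b)
    if (!length(inside)) next
    lo <- max(1L, inside[1] - 1L)
    hi <- min(n, inside[length(inside)] + 1L)
    mask[inside] <- TRUE
    for (ax in bit_cols <- axes) {
      v <- out[[ax]]
      v[inside] <- approx(x = t[c(lo, hi)], y = v[c(lo, hi)],
                          xout = t[inside])$y
      data.table::set(out, j = ax, value = v)
    }
  }
  nrm <- sqrt(out$gaze_dir_x^2 + out$gaze_dir_y^2 + out$gaze_dir_z^2)
  nrm[nrm == 0] <- 1
  data.table::set(out, j = "gaze_dir_x", value = out$gaze_dir_x / nrm)
  data.table::set(out, j = "gaze_dir_y", value = out$gaze_dir_y / nrm)
  data.table::set(out, j = "gaze_dir_z", value = out$gaze_dir_z / nrm)
  attr(out, "blink_mask") <- mask
  attr(out, "rate") <- attr(rec, "rate")
  out
}

#' Convert gaze direction to angular coordinates
#'
#' Head-fixed frame with z forward, x right, y up: azimuth = atan2(x, z),
#' elevation = atan2(y, sqrt(x^2 + z^2)), both in degrees.
#'
#' @param rec A `gh_recording` (ideally blink-interpolated).
#' @return data.frame with azimuth_deg, elevation_deg.
#' @export
gaze_to_angles <- function(rec) {
  x <- rec$gaze_dir_x; y <- rec$gaze_dir_y; z <- rec$gaze_dir_z
  nrm <- sqrt(x^2 + y^2 + z^2)
  if (any(nrm == 0)) stop("zero-norm gaze direction")
  r2d <- 180 / pi
  data.frame(azimuth_deg = atan2(x, z) * r2d,
             elevation_deg = atan2(y, sqrt(x^2 + z^2)) * r2d)
}

#' Inverse of [gaze_to_angles()]
#'
#' @param azimuth_deg,elevation_deg Angles in degrees.
#' @return Matrix of unit gaze vectors (columns x, y, z).
#' @export
angles_to_gaze <- function(azimuth_deg, elevation_deg) {
  d2r <- pi / 180
  az <- azimuth_deg * d2r; el <- elevation_deg * d2r
  cbind(x = sin(az) * cos(el), y = sin(el), z = cos(az) * cos(el))
}

#' Smoothed 2D angular velocity
#'
#' First-difference velocity (degrees/s) followed by a centered moving
#' average (default five samples, 55 ms at 90 Hz); the output keeps the input
#' length (backward difference with the first value repeated; shrinking
#' averaging windows at the edges).
#'
#' @param angles data.frame from [gaze_to_angles()].
#' @param rate Sampling rate (Hz).
#' @param window Moving-average length in samples (odd).
#' @return data.frame with vx, vy (deg/s).
#' @export
compute_smoothed_velocity <- function(angles, rate, window = 5L) {
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  n <- nrow(angles)
  stopifnot(n >= window + 1L)
  vx <- c(NA, diff(angles$azimuth_deg)) * rate
  vy <- c(NA, diff(angles$elevation_deg)) * rate
  vx[1] <- vx[2]; vy[1] <- vy[2]
  data.frame(vx = moving_average(vx, window), vy = moving_average(vy, window))
}

#' Median-based velocity thresholds
#'
#' Engbert-Kliegl robust scale per axis, sigma = sqrt(median(v^2) -
#' median(v)^2), multiplied by `lambda_mult` (default 6). Computed per trial.
#'
#' @param velocity data.frame with vx, vy for one trial.
#' @param lambda_mult Threshold multiplier.
#' @param trial Trial label used in error messages.
#' @return Named vector c(eta_x, eta_y) in deg/s.
#' @export
estimate_thresholds <- function(velocity, lambda_mult = 6, trial = NA) {
  stopifnot(nrow(velocity) >= 10L)
  sig <- vapply(velocity[, c("vx", "vy")], function(v) {
    s2 <- median(v^2) - median(v)^2
    sqrt(max(s2, 0))
  }, numeric(1))
  if (any(sig == 0))
    stop("degenerate velocity (sigma = 0) in trial ", trial)
  c(eta_x = lambda_mult * sig[[1]], eta_y = lambda_mult * sig[[2]])
}

#' Detect saccades by elliptic velocity-threshold crossing
#'
#' A saccade is a maximal run of samples with `(vx/eta_x)^2 + (vy/eta_y)^2 >
#' 1` lasting at least `min_samples` (default 2, i.e. 22 ms at 90 Hz). Events
#' whose run comes within one sample of a blink-interpolation window are
#' discarded.
#'
#' Smoothing widens each velocity excursion by the half-window, biasing the
#' first crossing early; when the raw (unsmoothed) velocity is supplied, the
#' onset is refined to the first sample inside the run where the raw
#' elliptic criterion itself exceeds 1.
#'
#' @param velocity data.frame with vx, vy (one trial).
#' @param thresholds Output of [estimate_thresholds()].
#' @param time Sample times (s), same length as velocity.
#' @param angles Angles (deg) used to measure amplitude (optional).
#' @param min_samples Minimum run length.
#' @param blink_mask Logical blink-interpolation mask (optional).
#' @param raw_velocity Unsmoothed velocity data.frame (optional, onset
#'   refinement).
#' @param raw_thresholds Thresholds estimated on the raw velocity, used for
#'   the refinement criterion (defaults to `thresholds`).
#' @return data.frame of events: onset_s, duration_s, peak_vel, amplitude_deg,
#'   onset_idx.
#' @export
detect_saccades <- function(velocity, thresholds, time, angles = NULL,
                            min_samples = 2L, blink_mask = NULL,
                            raw_velocity = NULL, raw_thresholds = thresholds) {
  crit <- (velocity$vx / thresholds[["eta_x"]])^2 +
    (velocity$vy / thresholds[["eta_y"]])^2 > 1
  crit[is.na(crit)] <- FALSE
  r <- rle(crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_samples
  starts <- starts[keep]; ends <- ends[keep]
  if (!is.null(blink_mask) && length(starts)) {
    near_blink <- vapply(seq_along(starts), function(i) {
      lo <- max(1L, starts[i] - 1L)
      hi <- min(length(blink_mask), ends[i] + 1L)
      any(blink_mask[lo:hi])
    }, logical(1))
    starts <- starts[!near_blink]; ends <- ends[!near_blink]
  }
  if (!is.null(raw_velocity) && length(starts)) {
    raw_speed <- sqrt(raw_velocity$vx^2 + raw_velocity$vy^2)
    # noise floor: the raw-threshold ellipse radii are lambda * sigma_median
    noise_floor <- 0.5 * sqrt(raw_thresholds[["eta_x"]]^2 +
                                raw_thresholds[["eta_y"]]^2)
    for (i in seq_along(starts)) {
      seg <- raw_speed[starts[i]:ends[i]]
      thr <- max(max(seg, na.rm = TRUE) / 4, noise_floor)
      hit <- which(seg >= thr)
      if (length(hit)) starts[i] <- starts[i] + hit[1] - 1L
    }
  }
  n <- length(starts)
  speed <- sqrt(velocity$vx^2 + velocity$vy^2)
  rate <- 1 / median(diff(time))
  amp <- rep(NA_real_, n)
  if (!is.null(angles) && n) {
    amp <- vapply(seq_len(n), function(i) {
      a0 <- max(1L, starts[i] - 1L)
      a1 <- min(nrow(angles), ends[i] + 1L)
      sqrt((angles$azimuth_deg[a1] - angles$azimuth_deg[a0])^2 +
             (angles$elevation_deg[a1] - angles$elevation_deg[a0])^2)
    }, numeric(1))
  }
  data.frame(
    onset_s = time[starts],
    duration_s = (ends - starts + 1L) / rate,
    peak_vel = vapply(seq_len(n), function(i) max(speed[starts[i]:ends[i]]),
                      numeric(1)),
    amplitude_deg = amp,
    onset_idx = starts)
}

#' Full saccade detection on a tracking recording
#'
#' Blink detection and interpolation, angular conversion, velocity smoothing,
#' per-trial threshold estimation and elliptic-crossing detection, in one
#' call.
#'
#' @param rec A `gh_recording`.
#' @param params List of detection tunables (see [analysis_config()]
#'   `$saccade`).
#' @param frame "head" (default) detects on head-fixed gaze direction.
#' @return data.frame of saccade events with trial_id.
#' @export
detect_saccades_recording <- function(rec, params = analysis_config()$saccade,
                                      frame = c("head", "world")) {
  frame <- match.arg(frame)
  rate <- attr(rec, "rate") %||% round(1 / median(diff(rec$time_s)))
  blinks <- detect_blinks(rec, params$blink_jump)
  reci <- interpolate_blinks(rec, blinks)
  mask <- attr(reci, "blink_mask")
  angles <- gaze_to_angles(reci)
  out <- list()
  for (tr in setdiff(unique(reci$trial_id), 0L)) {
    sel <- which(reci$trial_id == tr)
    if (length(sel) < params$smooth_window + 2L) next
    a <- angles[sel, ]
    v <- compute_smoothed_velocity(a, rate, params$smooth_window)
    vraw <- compute_smoothed_velocity(a, rate, 1L)
    eta <- tryCatch(estimate_thresholds(v, params$lambda_mult, trial = tr),
                    error = function(e) NULL)
    if (is.null(eta)) next
    eta_raw <- tryCatch(estimate_thresholds(vraw, params$lambda_mult,
                                            trial = tr),
                        error = function(e) eta)
    ev <- detect_saccades(v, eta, reci$time_s[sel], a,
                          min_samples = params$min_samples,
                          blink_mask = mask[sel], raw_velocity = vraw,
                          raw_thresholds = eta_raw)
    if (nrow(ev)) { ev$trial_id <- tr; out[[length(out) + 1L]] <- ev }
  }
  if (!length(out))
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak_vel = numeric(0), amplitude_deg = numeric(0),
                      onset_idx = integer(0), trial_id = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
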