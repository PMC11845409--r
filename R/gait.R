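#' Detect footfall troughs in vertical head position
#'
#' Zero-phase low-pass (default 6 Hz) and linear detrend per trial, then
#' local minima with a minimum separation (default 0.35 s) and a prominence
#' of at least `prominence_frac` (default 25%) of the trial's median
#' peak-to-trough amplitude. Head height is minimal at footfall
#' (double-support stance), so troughs delimit steps.
#'
#' @param head_z Vertical head position (m) for one trial.
#' @param time Sample times (s).
#' @param rate Sampling rate (Hz).
#' @param params Gait tunables (see [analysis_config()] `$gait`).
#' @return List: `trough_times`, `trough_idx`, `peak_times`,
#'   `step_durations`, `step_ok` (within duration bounds), `usable`.
#' @export
detect_troughs <- function(head_z, time, rate,
                           params = analysis_config()$gait) {
  n <- length(head_z)
  if (n < rate) stop("trial shorter than 1 s")
  x <- fft_filter(head_z, rate, high = params$lowpass_hz)
  x <- linear_detrend(x)
  if (sd(x) < 1e-12)
    return(list(trough_times = numeric(0), trough_idx = integer(0),
                peak_times = numeric(0), step_durations = numeric(0),
                step_ok = logical(0), usable = FALSE, reason = "flat"))
  mins <- which(diff(sign(diff(x))) > 0) + 1L
  maxs <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(mins) < 2L)
    return(list(trough_times = numeric(0), trough_idx = integer(0),
                peak_times = time[maxs], step_durations = numeric(0),
                step_ok = logical(0), usable = FALSE, reason = "too few troughs"))
  # prominence: height of the lower flanking peak above the trough
  prom <- vapply(mins, function(i) {
    lp <- maxs[maxs < i]; rp <- maxs[maxs > i]
    lv <- if (length(lp)) x[max(lp)] else max(x[seq_len(i)])
    rv <- if (length(rp)) x[min(rp)] else max(x[i:n])
    min(lv, rv) - x[i]
  }, numeric(1))
  med_amp <- median(prom[prom > 0])
  keep <- prom >= params$prominence_frac * med_amp
  mins <- mins[keep]; prom <- prom[keep]
  # enforce minimum separation, keeping the deeper trough
  min_sep <- params$min_separation_s
  if (length(mins) > 1L) {
    ord <- order(x[mins])            # deepest first
    sel <- logical(0); chosen <- integer(0)
    for (i in ord) {
      ti <- time[mins[i]]
      if (!length(chosen) || all(abs(time[mins[chosen]] - ti) >= min_sep))
        chosen <- c(chosen, i)
    }
    mins <- sort(mins[chosen])
  }
  if (length(mins) < 2L)
    return(list(trough_times = time[mins], trough_idx = mins,
                peak_times = time[maxs], step_durations = numeric(0),
                step_ok = logical(0), usable = FALSE, reason = "too few troughs"))
  # sub-sample refinement: least-squares cubic over an adaptive window of
  # 16% of the shorter adjacent step on each side; the cubic term absorbs
  # the curvature asymmetry of unequal steps, the window averages noise
  dt <- 1 / rate
  med_d <- median(diff(time[mins]))
  tt <- time[mins]
  for (j in seq_along(mins)) {
    i <- mins[j]
    dl <- if (j > 1L) time[i] - time[mins[j - 1L]] else med_d
    dr <- if (j < length(mins)) time[mins[j + 1L]] - time[i] else med_d
    k <- max(4L, round(0.16 * min(dl, dr) * rate))
    lo <- max(1L, i - k); hi <- min(n, i + k)
    ii <- (lo:hi) - i
    cf <- stats::lm.fit(cbind(1, ii, ii^2, ii^3), x[lo:hi])$coefficients
    if (any(!is.finite(cf))) next
    a <- 3 * cf[4]; b <- 2 * cf[3]; cc <- cf[2]
    d <- if (abs(a) < 1e-12) {
      if (b > 0) -cc / b else 0
    } else {
      disc <- b^2 - 4 * a * cc
      if (disc < 0) 0 else {
        r <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
        r <- r[2 * cf[3] + 6 * cf[4] * r > 0]      # minima only
        if (!length(r)) 0 else r[which.min(abs(r))]
      }
    }
    tt[j] <- time[i] + max(min(d, k), -k) * dt
  }
  durs <- diff(tt)
  ok <- durs >= params$step_bounds_s[1] & durs <= params$step_bounds_s[2]
  list(trough_times = tt, trough_idx = mins, peak_times = time[maxs],
       step_durations = durs, step_ok = ok, usable = TRUE, reason = NA_character_)
}

#' Extract gait from a tracking recording
#'
#' Runs [detect_troughs()] per trial and assembles a step table.
#'
#' @param rec A `gh_recording`.
#' @param params Gait tunables.
#' @return List of class `step_table`: `troughs` (data.frame trial_id,
#'   time), `steps` (trial_id, start_s, end_s, duration_s, ok), `trials`
#'   (trial_id, usable, reason).
#' @export
extract_gait <- function(rec, params = analysis_config()$gait) {
  rate <- attr(rec, "rate") %||% round(1 / median(diff(rec$time_s)))
  troughs <- list(); steps <- list(); trials <- list()
  for (tr in setdiff(unique(rec$trial_id), 0L)) {
    sel <- rec$trial_id == tr
    res <- tryCatch(
      detect_troughs(rec$head_z[sel], rec$time_s[sel], rate, params),
      error = function(e) list(usable = FALSE, reason = conditionMessage(e),
                               trough_times = numeric(0),
                               step_durations = numeric(0),
                               step_ok = logical(0)))
    trials[[length(trials) + 1L]] <-
      data.frame(trial_id = tr, usable = res$usable,
                 reason = res$reason %||% NA_character_)
    if (length(res$trough_times))
      troughs[[length(troughs) + 1L]] <-
        data.frame(trial_id = tr, time = res$trough_times)
    if (length(res$step_durations))
      steps[[length(steps) + 1L]] <- data.frame(
        trial_id = tr, start_s = head(res$trough_times, -1L),
        end_s = tail(res$trough_times, -1L),
        duration_s = res$step_durations, ok = res$step_ok)
  }
  structure(list(
    troughs = if (length(troughs)) do.call(rbind, troughs) else
      data.frame(trial_id = integer(0), time = numeric(0)),
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(trial_id = integer(0), start_s = numeric(0),
                 end_s = numeric(0), duration_s = numeric(0), ok = logical(0)),
    trials = do.call(rbind, trials)), class = "step_table")
}

#' Build stride windows from troughs
#'
#' A stride spans two consecutive steps (three consecutive troughs). With the
#' default one-step-overlap convention every trough triple (i, i+1, i+2)
#' defines a stride; `"disjoint"` uses non-overlapping triples. Strides
#' containing a step outside the duration bounds are excluded.
#'
#' @param steps A `step_table` from [extract_gait()].
#' @param convention "one-step-overlap" or "disjoint".
#' @return data.frame of class `stride_segmentation`: trial_id, start_s,
#'   mid_s, end_s.
#' @export
build_strides <- function(steps, convention = c("one-step-overlap", "disjoint")) {
  convention <- match.arg(convention)
  out <- list()
  st <- steps$steps
  for (tr in unique(st$trial_id)) {
    s <- st[st$trial_id == tr, ]
    if (nrow(s) < 2L) next
    idx <- if (convention == "one-step-overlap") seq_len(nrow(s) - 1L)
           else seq(1L, nrow(s) - 1L, by = 2L)
    for (i in idx) {
      if (!s$ok[i] || !s$ok[i + 1L]) next
      out[[length(out) + 1L]] <- data.frame(
        trial_id = tr, start_s = s$start_s[i], mid_s = s$end_s[i],
        end_s = s$end_s[i + 1L])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(trial_id = integer(0), start_s = numeric(0),
               mid_s = numeric(0), end_s = numeric(0))
  rownames(res) <- NULL
  structure(res, class = c("stride_segmentation", "data.frame"),
            convention = convention)
}

#' Resample a per-stride series to a fixed grid
#'
#' Linear interpolation of `(time, values)` onto `n` equally spaced points
#' across the stride window (default 200 points, 0.5% increments of stride
#' completion).
#'
#' @param time,values The series.
#' @param start_s,end_s Stride window.
#' @param n Number of grid points.
#' @return Numeric vector of length `n`.
#' @export
resample_stride <- function(time, values, start_s, end_s, n = 200L) {
  if (start_s < min(time) || end_s > max(time))
    stop("stride window outside the series span")
  grid <- seq(start_s, end_s, length.out = n)
  approx(time, values, xout = grid)$y
}

#' Assign event times to stride percentiles
#'
#' Each event maps to every stride containing it (at most two under the
#' one-step-overlap convention); the percentile is linear in time within the
#' stride, in \[0, 100). The percentile within the containing step is also
#' returned. Events outside all strides are dropped; their count is recorded
#' in the `n_dropped` attribute.
#'
#' @param event_times Event onset times (s).
#' @param strides A `stride_segmentation`.
#' @return data.frame: event_time, stride_idx, trial_id, pct, step_pct.
#' @export
assign_phase <- function(event_times, strides) {
  out <- list()
  assigned <- rep(FALSE, length(event_times))
  for (i in seq_len(nrow(strides))) {
    s0 <- strides$start_s[i]; sm <- strides$mid_s[i]; s1 <- strides$end_s[i]
    sel <- which(event_times >= s0 & event_times < s1)
    if (!length(sel)) next
    assigned[sel] <- TRUE
    tt <- event_times[sel]
    step_pct <- ifelse(tt < sm, 100 * (tt - s0) / (sm - s0),
                       100 * (tt - sm) / (s1 - sm))
    out[[length(out) + 1L]] <- data.frame(
      event_time = tt, stride_idx = i, trial_id = strides$trial_id[i],
      pct = 100 * (tt - s0) / (s1 - s0), step_pct = step_pct)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(event_time = numeric(0), stride_idx = integer(0),
               trial_id = integer(0), pct = numeric(0), step_pct = numeric(0))
  rownames(res) <- NULL
  attr(res, "n_dropped") <- sum(!assigned)
  res
}

#' Automated trial exclusion
#'
#' Replaces the published visual inspection with fixed criteria: a trial is
#' excluded when tracking dropout exceeds `max_dropout_s` (default 0.25 s),
#' when more than `max_bad_step_frac` (default 20%) of its steps fall outside
#' the duration bounds, or when fewer than 3 troughs were found.
#'
#' @param steps A `step_table`.
#' @param dropouts Dropout table from [read_tracking()] (start_s, end_s), or
#'   NULL.
#' @param params Gait tunables.
#' @param trial_windows data.frame trial_id, start_s, end_s used to attribute
#'   dropouts to trials (optional; inferred from steps if NULL).
#' @return data.frame: trial_id, excluded, reason.
#' @export
exclude_bad_trials <- function(steps, dropouts = NULL,
                               params = analysis_config()$gait,
                               trial_windows = NULL) {
  res <- list()
  for (tr in steps$trials$trial_id) {
    s <- steps$steps[steps$steps$trial_id == tr, ]
    n_troughs <- sum(steps$troughs$trial_id == tr)
    reason <- NA_character_
    if (!is.null(dropouts) && nrow(dropouts)) {
      tw <- if (!is.null(trial_windows)) trial_windows[
        trial_windows$trial_id == tr, ] else NULL
      dur <- dropouts$end_s - dropouts$start_s
      inside <- if (!is.null(tw) && nrow(tw))
        dropouts$start_s >= tw$start_s & dropouts$end_s <= tw$end_s
      else rep(TRUE, nrow(dropouts))
      if (any(dur[inside] > params$max_dropout_s)) reason <- "dropout"
    }
    if (is.na(reason) && n_troughs < 3L) reason <- "too few troughs"
    if (is.na(reason) && nrow(s) > 0L &&
        mean(!s$ok) > params$max_bad_step_frac) reason <- "duration bounds"
    res[[length(res) + 1L]] <-
      data.frame(trial_id = tr, excluded = !is.na(reason), reason = reason)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
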