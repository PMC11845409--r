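#' Task-design constants
#'
#' Fixed parameters of the walking RSVP paradigm the generator emulates:
#' walkway lengths, trial duration, stimulus geometry and presentation
#' timing, and the nominal acquisition rates.
#'
#' @return Named list of design constants.
#' @export
design_constants <- function() {
  list(
    walkway_natural_m   = 7,
    walkway_slow_m      = 3.5,
    trial_duration_s    = 5,
    stimulus_size_m     = 0.1225,  # 12.25 cm square
    stimulus_distance_m = 1,
    image_period_s      = 0.2,     # 100 ms on + 100 ms gap
    tracking_rate_hz    = 90,
    eeg_rate_hz         = 300,
    conditions          = c("static", "slow", "natural"),
    walk_speed_ms       = c(static = 0, slow = 0.7, natural = 1.4)
  )
}

#' Walking-simulation parameters
#'
#' Step-duration statistics default to the condition-specific values observed
#' in overground walking at these speeds: slow walking mean 0.72 s (SD 0.09),
#' natural walking mean 0.61 s (SD 0.06). Durations are drawn i.i.d. from a
#' normal truncated to \[0.4, 1.2\] s, the physiological step range.
#'
#' @param condition "static", "slow" or "natural".
#' @param step_duration_mean,step_duration_sd Step duration distribution (s).
#' @param bob_amplitude Peak-to-trough vertical head excursion (m).
#' @param head_height_mean Mean head height (m).
#' @param n_trials Number of trials.
#' @param trial_duration Trial (RSVP stream) duration (s).
#' @param trial_gap Dead time between trials (s).
#' @param tracking_rate Tracking sampling rate (Hz).
#' @return Object of class `walk_params`.
#' @export
walk_params <- function(condition = c("natural", "slow", "static"),
                        step_duration_mean = NULL, step_duration_sd = NULL,
                        bob_amplitude = NULL, head_height_mean = 1.7,
                        n_trials = 100, trial_duration = 5, trial_gap = 1,
                        tracking_rate = 90) {
  condition <- match.arg(condition)
  defaults <- list(
    slow    = list(mean = 0.72, sd = 0.09, bob = 0.04),
    natural = list(mean = 0.61, sd = 0.06, bob = 0.05),
    static  = list(mean = 0.61, sd = 0.06, bob = 0)
  )[[condition]]
  p <- list(
    condition = condition,
    step_duration_mean = step_duration_mean %||% defaults$mean,
    step_duration_sd = step_duration_sd %||% defaults$sd,
    bob_amplitude = bob_amplitude %||% defaults$bob,
    head_height_mean = head_height_mean,
    n_trials = as.integer(n_trials),
    trial_duration = trial_duration,
    trial_gap = trial_gap,
    tracking_rate = tracking_rate,
    step_bounds = c(0.4, 1.2)
  )
  assert_that(p$tracking_rate > 0, "tracking_rate must be positive")
  assert_that(p$step_duration_mean > 2 / p$tracking_rate,
              "step_duration_mean must exceed two tracking samples")
  assert_that(p$bob_amplitude >= 0, "bob_amplitude must be non-negative")
  assert_that(p$n_trials >= 1, "need at least one trial")
  structure(p, class = "walk_params")
}

#' Saccade-simulation parameters
#'
#' The saccade train is an inhomogeneous Bernoulli process on the tracking
#' grid with rate `lambda(t) = base_rate * (1 + modulation_depth *
#' cos(2*pi*modulation_freq*phi(t)/100 + modulation_phase))`, `phi(t)` the
#' true stride percentile. `modulation_freq = 2` cycles per stride equals the
#' step rate. The base rate is a free simulation parameter (default 1.5/s).
#'
#' @param base_rate Saccades per second (lambda0).
#' @param modulation_depth m in \[0, 1\].
#' @param modulation_freq Cycles per stride.
#' @param modulation_phase Phase offset phi0 (rad).
#' @param amplitude_mean,amplitude_sd Saccade amplitude distribution (deg),
#'   truncated below at 0.5 deg.
#' @param saccade_duration Saccade duration (s).
#' @param gaze_noise_sd Fixation noise SD per axis (deg).
#' @param blink_rate Blinks per minute.
#' @return Object of class `saccade_params`.
#' @export
saccade_params <- function(base_rate = 1.5, modulation_depth = 0,
                           modulation_freq = 2, modulation_phase = 0,
                           amplitude_mean = 3, amplitude_sd = 1,
                           saccade_duration = 0.044, gaze_noise_sd = 0.05,
                           blink_rate = 3) {
  assert_that(base_rate >= 0, "base_rate must be non-negative")
  assert_that(modulation_depth >= 0 && modulation_depth <= 1,
              "modulation_depth must lie in [0, 1] (rate would go negative)")
  assert_that(modulation_freq > 0, "modulation_freq must be positive")
  structure(list(base_rate = base_rate, modulation_depth = modulation_depth,
                 modulation_freq = modulation_freq,
                 modulation_phase = modulation_phase,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 saccade_duration = saccade_duration,
                 gaze_noise_sd = gaze_noise_sd, blink_rate = blink_rate),
            class = "saccade_params")
}

#' EEG-simulation parameters
#'
#' Each scalp channel is 1/f background noise plus a band-limited oscillation
#' whose instantaneous amplitude follows the step cycle:
#' `(1 + gait_mod_depth * cos(2*pi*phi_step(t)/100 + gait_mod_phase))`.
#'
#' @param eeg_rate Sampling rate (Hz).
#' @param background Background noise SD (uV).
#' @param gait_band Two-element band (Hz) of the gait-modulated oscillation,
#'   inside \[3, 40\].
#' @param gait_amp Oscillation SD at unit envelope (uV).
#' @param gait_mod_depth Envelope modulation depth in \[0, 1\].
#' @param gait_mod_phase Envelope phase (rad); pi puts the power peak at 50%
#'   of the step cycle.
#' @param saccade_transient_amp Amplitude (uV) of a brief transient added at
#'   each saccade onset (0 disables).
#' @return Object of class `eeg_params`.
#' @export
eeg_params <- function(eeg_rate = 300, background = 10,
                       gait_band = c(8, 12), gait_amp = 5,
                       gait_mod_depth = 0, gait_mod_phase = 0,
                       saccade_transient_amp = 0) {
  assert_that(length(gait_band) == 2 && gait_band[1] < gait_band[2] &&
                gait_band[1] >= 3 && gait_band[2] <= 40,
              "gait_band must satisfy 3 <= f_lo < f_hi <= 40")
  assert_that(gait_mod_depth >= 0 && gait_mod_depth <= 1,
              "gait_mod_depth must lie in [0, 1]")
  structure(list(eeg_rate = eeg_rate, background = background,
                 gait_band = gait_band, gait_amp = gait_amp,
                 gait_mod_depth = gait_mod_depth,
                 gait_mod_phase = gait_mod_phase,
                 saccade_transient_amp = saccade_transient_amp),
            class = "eeg_params")
}

#' Canonical channel montage
#'
#' The 19 scalp positions of the international 10-20 system plus the earlobe
#' references A1/A2.
#'
#' @return Character vector of 21 channel labels.
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz", "C4",
    "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2", "A1", "A2")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Step-count function u(t) within one trial: piecewise linear, one unit per
# step, anchored so that a trough (integer u) falls half a step after trial
# onset. Returns boundaries b (virtual trough before onset included) and
# durations d covering [start, end].
make_trial_steps <- function(start, duration, mean, sd, bounds) {
  d1 <- rtruncnorm1(1L, mean, sd, bounds[1], bounds[2])
  b <- start - 0.5 * d1
  d <- d1
  while (b + sum(d) < start + duration) {
    d <- c(d, rtruncnorm1(1L, mean, sd, bounds[1], bounds[2]))
  }
  list(b0 = b, d = d, bounds_times = b + cumsum(c(0, d)))
}

# u(t) for one trial's step structure; NA outside [b0, last boundary].
step_count_at <- function(steps, t) {
  bt <- steps$bounds_times
  idx <- findInterval(t, bt)
  u <- rep(NA_real_, length(t))
  ok <- idx >= 1L & idx <= length(steps$d)
  u[ok] <- (idx[ok] - 1L) + (t[ok] - bt[idx[ok]]) / steps$d[idx[ok]]
  u
}

#' Simulate a walking session's head trajectory
#'
#' Per trial, vertical head position is `head_height_mean - (bob_amplitude/2)
#' * cos(2*pi*u(t))` where `u(t)` accumulates one unit per step, so troughs
#' (footfalls, double-support stance) coincide exactly with the recorded
#' ground-truth trough times. Horizontal position advances at the condition's
#' walking speed during trials. Static trials have a flat trajectory.
#'
#' @param params A [walk_params()] object.
#' @param seed Integer seed.
#' @return List with `tracking` (data.table: time_s, head_x/y/z, trial_id;
#'   trial_id 0 between trials), and `truth` (trial table, trough times, step
#'   structure per trial).
#' @export
simulate_walk <- function(params, seed = 1L) {
  stopifnot(inherits(params, "walk_params"))
  assert_that(params$trial_duration >= params$step_bounds[1],
              "trial_duration shorter than a single step")
  p <- params
  dt <- 1 / p$tracking_rate
  trial_len <- p$trial_duration + p$trial_gap
  total <- p$n_trials * trial_len
  time <- seq(0, total - dt, by = dt)
  n <- length(time)
  head_z <- rep(p$head_height_mean, n)
  head_x <- numeric(n)
  head_y <- numeric(n)
  trial_id <- integer(n)
  speed <- design_constants()$walk_speed_ms[[p$condition]]
  walking <- p$condition != "static"

  trials <- data.frame(trial_id = seq_len(p$n_trials),
                       start = (seq_len(p$n_trials) - 1L) * trial_len,
                       end = (seq_len(p$n_trials) - 1L) * trial_len +
                         p$trial_duration)
  steps <- vector("list", p$n_trials)
  troughs <- list()
  with_seed(seed, {
    xoff <- 0
    for (k in seq_len(p$n_trials)) {
      s <- trials$start[k]; e <- trials$end[k]
      in_tr <- time >= s & time < e
      trial_id[in_tr] <- k
      if (walking) {
        st <- make_trial_steps(s, p$trial_duration, p$step_duration_mean,
                               p$step_duration_sd, p$step_bounds)
        steps[[k]] <- st
        u <- step_count_at(st, time[in_tr])
        head_z[in_tr] <- p$head_height_mean -
          0.5 * p$bob_amplitude * cos(2 * pi * u)
        head_x[in_tr] <- xoff + speed * (time[in_tr] - s)
        xoff <- xoff + speed * p$trial_duration
        tt <- st$bounds_times
        tt <- tt[tt > s & tt < e]
        if (length(tt))
          troughs[[length(troughs) + 1L]] <-
            data.frame(trial_id = k, time = tt)
        head_x[!in_tr & time >= e & time < e + p$trial_gap] <- xoff
      }
    }
  })
  # carry forward horizontal position through gaps
  if (walking) {
    for (i in seq_len(n)[-1]) if (trial_id[i] == 0L && head_x[i] == 0)
      head_x[i] <- head_x[i - 1L]
  }
  trough_df <- if (length(troughs)) do.call(rbind, troughs) else
    data.frame(trial_id = integer(0), time = numeric(0))
  step_durs <- if (walking)
    unlist(lapply(seq_len(p$n_trials), function(k) {
      st <- steps[[k]]
      tt <- st$bounds_times
      inside <- tt > trials$start[k] & tt < trials$end[k]
      if (sum(inside) < 2L) return(numeric(0))
      diff(tt[inside])
    })) else numeric(0)
  list(
    tracking = data.table::data.table(time_s = time, head_x = head_x,
                                      head_y = head_y, head_z = head_z,
                                      trial_id = trial_id),
    truth = list(condition = p$condition, params = unclass(p),
                 rate = p$tracking_rate, trials = trials, steps = steps,
                 trough_times = trough_df, step_durations = step_durs)
  )
}

# True step percentile (0-100) and stride percentile (0-100, stride = two
# steps counted from each footfall) at arbitrary times; NA outside steps.
true_phases <- function(walk_truth, t) {
  trials <- walk_truth$trials
  u <- rep(NA_real_, length(t))
  idx <- findInterval(t, trials$start)
  for (k in unique(idx[idx >= 1])) {
    sel <- idx == k & t < trials$end[k]
    if (!any(sel) || is.null(walk_truth$steps[[k]])) next
    u[sel] <- step_count_at(walk_truth$steps[[k]], t[sel])
  }
  list(step_pct = 100 * (u %% 1), stride_pct = 100 * (u %% 2) / 2, u = u)
}

raised_cosine_step <- function(frac) 0.5 * (1 - cos(pi * pmin(pmax(frac, 0), 1)))

#' Simulate gaze streams with gait-modulated saccades
#'
#' Saccade onsets follow an inhomogeneous Bernoulli process on the tracking
#' grid (rate modulated by true stride percentile, see [saccade_params()]);
#' each saccade is a smooth raised-cosine angular displacement superposed on
#' Gaussian fixation noise. Blinks are inserted as 1.0-m gaze-origin jumps
#' lasting 100-300 ms. No saccade is generated inside a blink's +/-100 ms
#' interpolation window (such events would be uninterpretable downstream).
#'
#' @param walk Output of [simulate_walk()].
#' @param params A [saccade_params()] object.
#' @param seed Integer seed.
#' @return List with `gaze` (data.table: time_s, gaze_origin_x/y/z,
#'   gaze_dir_x/y/z), `saccades` (truth table with onset_s, amplitude_deg,
#'   true step/stride percentiles) and `blinks` (onset_s, offset_s).
#' @export
simulate_gaze <- function(walk, params, seed = 1L) {
  stopifnot(inherits(params, "saccade_params"))
  tr <- walk$tracking
  t <- tr$time_s
  n <- length(t)
  rate <- walk$truth$rate
  dt <- 1 / rate
  ph <- true_phases(walk$truth, t)
  in_trial <- tr$trial_id > 0L
  lam <- numeric(n)
  modulated <- in_trial & !is.na(ph$stride_pct)
  lam[modulated] <- params$base_rate *
    (1 + params$modulation_depth *
       cos(2 * pi * params$modulation_freq * ph$stride_pct[modulated] / 100 +
             params$modulation_phase))
  lam[in_trial & !modulated] <- params$base_rate  # static trials: unmodulated
  if (any(lam < 0)) stop("negative saccade rate: modulation_depth too large")

  dur_samp <- max(2L, round(params$saccade_duration * rate))
  with_seed(seed, {
    # blinks first, so saccades can avoid them
    p_blink <- (params$blink_rate / 60) * dt
    blink_on <- which(in_trial & runif(n) < p_blink)
    blink_len <- round(runif(length(blink_on), 0.1, 0.3) * rate)
    blink_mask <- rep(FALSE, n)
    pad <- round(0.1 * rate)
    for (i in seq_along(blink_on)) {
      a <- blink_on[i]; b <- min(n, blink_on[i] + blink_len[i])
      blink_mask[max(1L, a - pad):min(n, b + pad)] <- TRUE
    }
    onset_ok <- runif(n) < lam * dt & !blink_mask
    # physiological refractory: no two onsets within 120 ms (also keeps the
    # velocity excursions of neighbouring saccades from merging)
    refract <- max(dur_samp + 2L, round(0.12 * rate))
    keep <- which(onset_ok)
    if (length(keep) > 1L) {
      last <- keep[1]; sel <- keep[1]
      for (i in keep[-1]) if (i - last > refract) { sel <- c(sel, i); last <- i }
      keep <- sel
    }
    amp <- pmax(0.5, rnorm(length(keep), params$amplitude_mean,
                           params$amplitude_sd))
    dir_angle <- runif(length(keep), 0, 2 * pi)

    az <- rnorm(n, 0, params$gaze_noise_sd)
    el <- rnorm(n, 0, params$gaze_noise_sd)
    base_az <- numeric(n); base_el <- numeric(n)
    prof <- raised_cosine_step(seq_len(dur_samp) / dur_samp)
    cur_az <- 0; cur_el <- 0
    events <- list()
    for (i in seq_along(keep)) {
      k <- keep[i]
      # bias direction toward recentering to keep gaze bounded
      tgt <- atan2(-cur_el, -cur_az)
      ang <- if (sqrt(cur_az^2 + cur_el^2) > 4) tgt else dir_angle[i]
      daz <- amp[i] * cos(ang); del <- amp[i] * sin(ang)
      seg <- k:min(n, k + dur_samp - 1L)
      base_az[seg] <- base_az[seg] + daz * prof[seq_along(seg)]
      base_el[seg] <- base_el[seg] + del * prof[seq_along(seg)]
      if (k + dur_samp <= n) {
        base_az[(k + dur_samp):n] <- base_az[(k + dur_samp):n] + daz
        base_el[(k + dur_samp):n] <- base_el[(k + dur_samp):n] + del
      }
      cur_az <- cur_az + daz; cur_el <- cur_el + del
      events[[i]] <- data.frame(
        onset_s = t[k], duration_s = dur_samp * dt, amplitude_deg = amp[i],
        trial_id = tr$trial_id[k], step_pct = ph$step_pct[k],
        stride_pct = ph$stride_pct[k])
    }
    az <- az + base_az; el <- el + base_el

    d2r <- pi / 180
    gx <- sin(az * d2r) * cos(el * d2r)
    gy <- sin(el * d2r)
    gz <- cos(az * d2r) * cos(el * d2r)
    ox <- tr$head_x + rnorm(n, 0, 0.001)
    oy <- tr$head_y + rnorm(n, 0, 0.001)
    oz <- tr$head_z + rnorm(n, 0, 0.001)
    blinks <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
    if (length(blink_on)) {
      for (i in seq_along(blink_on)) {
        a <- blink_on[i]; b <- min(n, blink_on[i] + blink_len[i])
        oy[a:b] <- oy[a:b] + 1.0
      }
      blinks <- data.frame(onset_s = t[blink_on],
                           offset_s = t[pmin(n, blink_on + blink_len)])
    }
    sacc <- if (length(events)) do.call(rbind, events) else
      data.frame(onset_s = numeric(0), duration_s = numeric(0),
                 amplitude_deg = numeric(0), trial_id = integer(0),
                 step_pct = numeric(0), stride_pct = numeric(0))
    list(gaze = data.table::data.table(
           time_s = t, gaze_origin_x = ox, gaze_origin_y = oy,
           gaze_origin_z = oz, gaze_dir_x = gx, gaze_dir_y = gy,
           gaze_dir_z = gz),
         saccades = sacc, blinks = blinks)
  })
}

one_over_f_noise <- function(n, rate, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  white <- rnorm(n)
  X <- fft(white)
  f <- c(seq_len(ceiling(n / 2)) - 1L, -rev(seq_len(floor(n / 2)))) * rate / n
  shape <- ifelse(abs(f) < 0.5, 0, 1 / sqrt(abs(f)))
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x * sd_target / sd(x)
}

band_noise <- function(n, rate, band) {
  x <- fft_filter(rnorm(n), rate, low = band[1], high = band[2], order = 8L)
  x / sd(x)
}

#' Simulate gait-modulated EEG
#'
#' Scalp channels carry 1/f background plus a band-limited oscillation whose
#' amplitude envelope follows the true step percentile; an optional brief
#' transient is added at each saccade onset. A1/A2 carry low-amplitude noise.
#' Trial-onset triggers (code 1) are emitted at every trial start.
#'
#' @param walk Output of [simulate_walk()].
#' @param saccades Saccade truth table from [simulate_gaze()] (may be NULL).
#' @param params An [eeg_params()] object.
#' @param seed Integer seed.
#' @return An `eeg_recording` (see [read_eeg()]) with ground-truth attributes.
#' @export
simulate_eeg <- function(walk, saccades, params, seed = 1L) {
  stopifnot(inherits(params, "eeg_params"))
  rate <- params$eeg_rate
  total <- max(walk$tracking$time_s) + 1 / walk$truth$rate
  t <- seq(0, total - 1 / rate, by = 1 / rate)
  n <- length(t)
  chans <- eeg_channels()
  ph <- true_phases(walk$truth, t)
  env <- rep(1, n)
  ok <- !is.na(ph$step_pct)
  env[ok] <- 1 + params$gait_mod_depth *
    cos(2 * pi * ph$step_pct[ok] / 100 + params$gait_mod_phase)
  data <- matrix(0, nrow = length(chans), ncol = n,
                 dimnames = list(chans, NULL))
  with_seed(seed, {
    # shared component emulates volume conduction: scalp channels correlate
    common_bg <- one_over_f_noise(n, rate, params$background)
    osc <- band_noise(n, rate, params$gait_band) * params$gait_amp * env
    for (ci in seq_along(chans)) {
      if (chans[ci] %in% c("A1", "A2")) {
        data[ci, ] <- rnorm(n, 0, 0.1 * params$background)
      } else {
        own <- one_over_f_noise(n, rate, params$background)
        data[ci, ] <- sqrt(0.5) * (common_bg + own) + osc
      }
    }
    if (params$saccade_transient_amp > 0 && !is.null(saccades) &&
        nrow(saccades)) {
      tw <- seq(0, 0.1, by = 1 / rate)
      wave <- params$saccade_transient_amp *
        sin(2 * pi * 15 * tw) * exp(-((tw - 0.05) / 0.02)^2)
      for (on in saccades$onset_s) {
        k <- round(on * rate) + 1L
        seg <- k:min(n, k + length(wave) - 1L)
        sc <- which(!chans %in% c("A1", "A2"))
        data[sc, seg] <- data[sc, seg] +
          matrix(wave[seq_along(seg)], nrow = length(sc),
                 ncol = length(seg), byrow = TRUE)
      }
    }
  })
  triggers <- data.frame(onset_s = walk$truth$trials$start, code = 1L)
  rec <- new_eeg_recording(data = data, channels = chans, rate = rate,
                           time = t, triggers = triggers)
  attr(rec, "truth") <- list(gait_band = params$gait_band,
                             gait_mod_depth = params$gait_mod_depth,
                             gait_mod_phase = params$gait_mod_phase)
  rec
}

#' Simulate and write a full session to disk
#'
#' Writes the tracking TSV, EEG TSV + trigger TSV, BIDS-style events TSV and
#' a ground-truth JSON, all reproducible from the seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param participant_id Participant label used as the file stem prefix.
#' @param walk,sacc,eeg Parameter objects ([walk_params()],
#'   [saccade_params()], [eeg_params()]).
#' @param seed Integer seed; split internally per stage.
#' @return A [recording_bundle()] with a `truth` attribute.
#' @export
simulate_session <- function(out_dir, participant_id = "sim01",
                             walk = walk_params("natural"),
                             sacc = saccade_params(),
                             eeg = eeg_params(), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- split_seed(seed, 3L)
  w <- simulate_walk(walk, seeds[1])
  g <- simulate_gaze(w, sacc, seeds[2])
  e <- simulate_eeg(w, g$saccades, eeg, seeds[3])

  stem <- file.path(out_dir, paste0(participant_id, "_", walk$condition))
  tracking <- cbind(w$tracking[, c("time_s", "head_x", "head_y", "head_z")],
                    g$gaze[, -1], trial_id = w$tracking$trial_id)
  tracking_path <- paste0(stem, "_tracking.tsv")
  data.table::fwrite(tracking, tracking_path, sep = "\t")
  eeg_path <- paste0(stem, "_eeg.tsv")
  write_eeg(e, eeg_path)
  events <- data.frame(onset = w$truth$trials$start,
                       duration = walk$trial_duration,
                       trial_type = "trial_onset",
                       trial_id = w$truth$trials$trial_id)
  events_path <- paste0(stem, "_events.tsv")
  data.table::fwrite(events, events_path, sep = "\t")

  truth <- list(condition = walk$condition, seed = seed,
                trough_times = w$truth$trough_times,
                step_durations = w$truth$step_durations,
                saccades = g$saccades, blinks = g$blinks,
                saccade_modulation = list(freq = sacc$modulation_freq,
                                          depth = sacc$modulation_depth,
                                          phase = sacc$modulation_phase),
                eeg_modulation = attr(e, "truth"))
  truth_path <- paste0(stem, "_truth.json")
  jsonlite::write_json(truth, truth_path, digits = 10, auto_unbox = TRUE,
                       dataframe = "columns")
  bundle <- recording_bundle(tracking_path = tracking_path,
                             eeg_path = eeg_path, events_path = events_path,
                             participant_id = participant_id,
                             condition = walk$condition,
                             tracking_rate = walk$tracking_rate,
                             eeg_rate = eeg$eeg_rate)
  attr(bundle, "truth") <- c(truth, list(walk_truth = w$truth))
  bundle
}
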