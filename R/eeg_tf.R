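scalp_channels <- function(rec) setdiff(rec$channels, c("A1", "A2"))

#' Preprocess an EEG recording
#'
#' Re-references scalp channels to the average of A1 and A2, applies a
#' zero-phase 0.1-40 Hz band-pass, and flags bad channels by a deviation
#' criterion (robust z-score of the channel SD > 5) and a correlation
#' criterion (best inter-channel correlation < 0.4 in more than 1% of 1-s
#' windows). Bad channels are recorded in `$bad_channels` and excluded from
#' downstream analysis.
#'
#' @param rec An `eeg_recording`.
#' @param cfg `$eeg` section of an [analysis_config()].
#' @return The preprocessed `eeg_recording`.
#' @export
preprocess_eeg <- function(rec, cfg = analysis_config()$eeg) {
  stopifnot(inherits(rec, "eeg_recording"))
  for (ref in c("A1", "A2"))
    if (!ref %in% rec$channels) stop("reference channel ", ref, " missing")
  ref <- colMeans(rec$data[c("A1", "A2"), , drop = FALSE])
  sc <- scalp_channels(rec)
  out <- rec
  for (ch in sc) {
    x <- rec$data[ch, ] - ref
    # order-12 magnitude response: > 20 dB down at 50 Hz for a 40-Hz edge
    out$data[ch, ] <- fft_filter(x, rec$rate, low = cfg$bandpass_hz[1],
                                 high = cfg$bandpass_hz[2], order = 12L)
  }
  sds <- apply(out$data[sc, , drop = FALSE], 1, sd)
  medsd <- median(sds); madsd <- stats::mad(sds)
  dev_bad <- if (madsd > 0) abs(sds - medsd) / madsd > 5 else sds != medsd
  win <- floor(rec$rate)
  nwin <- floor(ncol(out$data) / win)
  nwin <- min(nwin, 60L)  # 60 s suffices to judge correlation structure
  lowcorr <- matrix(FALSE, nrow = length(sc), ncol = nwin)
  for (w in seq_len(nwin)) {
    seg <- out$data[sc, ((w - 1L) * win + 1L):(w * win), drop = FALSE]
    cc <- suppressWarnings(stats::cor(t(seg)))
    diag(cc) <- NA
    best <- apply(abs(cc), 1, max, na.rm = TRUE)
    lowcorr[, w] <- best < 0.4
  }
  corr_bad <- rowMeans(lowcorr) > 0.01
  bad <- sc[dev_bad | corr_bad]
  if (length(bad) > length(sc) / 2)
    stop("more than 50% of channels are bad; aborting participant")
  out$bad_channels <- bad
  out
}

#' Epoch by trial onsets
#'
#' Epochs -100 ms to +6500 ms relative to each trigger, baseline-corrected
#' with the 100-ms pre-trial mean per channel. Epochs exceeding the recording
#' bounds are dropped and counted.
#'
#' @param rec A preprocessed `eeg_recording`.
#' @param onsets Trial onset times (s); defaults to the trigger table.
#' @param window Epoch window (s) relative to onset.
#' @return List of class `trial_epochs`: `epochs` (list of channel x time
#'   matrices), `onsets`, `n_dropped`, `time` (epoch time axis).
#' @export
epoch_trials <- function(rec, onsets = rec$triggers$onset_s,
                         window = c(-0.1, 6.5)) {
  rate <- rec$rate
  nsamp <- ncol(rec$data)
  w0 <- round(window[1] * rate); w1 <- round(window[2] * rate)
  base_n <- -w0
  epochs <- list(); kept <- numeric(0); dropped <- 0L
  for (on in onsets) {
    k <- round(on * rate) + 1L
    lo <- k + w0; hi <- k + w1
    if (lo < 1L || hi > nsamp) { dropped <- dropped + 1L; next }
    e <- rec$data[, lo:hi, drop = FALSE]
    if (base_n > 0) e <- e - rowMeans(e[, seq_len(base_n), drop = FALSE])
    epochs[[length(epochs) + 1L]] <- e
    kept <- c(kept, on)
  }
  structure(list(epochs = epochs, onsets = kept, n_dropped = dropped,
                 time = seq(w0, w1) / rate), class = "trial_epochs")
}

#' Epoch by steps
#'
#' Extracts one epoch per step from `pad` seconds before step onset to `pad`
#' seconds after step completion (default 600 ms each side), recording each
#' epoch's step window and its pooled standard deviation over channels and
#' time.
#'
#' @param rec A preprocessed `eeg_recording`.
#' @param steps data.frame with start_s, end_s (one row per step), e.g.
#'   `extract_gait(...)$steps`.
#' @param pad Padding (s) on each side.
#' @param channels Channels to include (default good scalp channels).
#' @return List of class `step_epochs`: `epochs`, `step` (start/end per
#'   epoch), `sd` (per-epoch pooled SD), `keep` (set by
#'   [reject_outlier_epochs()]).
#' @export
epoch_steps <- function(rec, steps, pad = 0.6,
                        channels = setdiff(scalp_channels(rec),
                                           rec$bad_channels)) {
  rate <- rec$rate
  nsamp <- ncol(rec$data)
  epochs <- list(); meta <- list()
  for (i in seq_len(nrow(steps))) {
    lo <- round((steps$start_s[i] - pad) * rate) + 1L
    hi <- round((steps$end_s[i] + pad) * rate) + 1L
    if (lo < 1L || hi > nsamp) next
    epochs[[length(epochs) + 1L]] <- rec$data[channels, lo:hi, drop = FALSE]
    meta[[length(meta) + 1L]] <- data.frame(
      start_s = steps$start_s[i], end_s = steps$end_s[i],
      t0 = (lo - 1L) / rate)
  }
  if (length(epochs) < 10L) warning("fewer than 10 step epochs: outlier quartiles unstable")
  structure(list(epochs = epochs, step = do.call(rbind, meta),
                 sd = vapply(epochs, sd, numeric(1)),
                 keep = rep(TRUE, length(epochs)),
                 channels = channels, rate = rate, pad = pad),
            class = "step_epochs")
}

#' Reject outlier epochs by the interquartile rule
#'
#' Flags epochs whose pooled SD lies strictly above Q3 + 1.5 IQR or below
#' Q1 - 1.5 IQR of the distribution of epoch SDs.
#'
#' @param ep A `step_epochs` (or any list with an `sd` field).
#' @return The input with `keep` updated.
#' @export
reject_outlier_epochs <- function(ep) {
  q <- quantile(ep$sd, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  ep$keep <- ep$sd <= q[2] + 1.5 * iqr & ep$sd >= q[1] - 1.5 * iqr
  ep
}

#' Morlet time-frequency grid
#'
#' 50 linearly spaced center frequencies from 3 to 40 Hz; the Gaussian
#' envelope's full-width at half-maximum shrinks linearly from 600 ms at the
#' lowest to 100 ms at the highest frequency.
#'
#' @param cfg `$eeg` section of an [analysis_config()].
#' @return List: `freqs` (Hz), `fwhm` (s).
#' @export
tf_grid <- function(cfg = analysis_config()$eeg) {
  freqs <- seq(cfg$tf_freqs[1], cfg$tf_freqs[2], length.out = cfg$tf_n)
  fwhm <- seq(cfg$fwhm_ms[1], cfg$fwhm_ms[2], length.out = cfg$tf_n) / 1000
  list(freqs = freqs, fwhm = fwhm)
}

#' Morlet wavelet time-frequency power
#'
#' Convolves each channel with complex Morlet wavelets implemented as
#' one-sided Gaussians in the frequency domain (sigma_f = 1 / (2*pi*sigma_t),
#' sigma_t = FWHM / (2*sqrt(2*log(2)))), normalized to unit peak gain so a
#' unit-amplitude sinusoid yields the same power (0.25) at every center
#' frequency. Power is the squared magnitude of the analytic signal.
#'
#' @param x Channel x time matrix (or vector) of one epoch.
#' @param rate Sampling rate (Hz).
#' @param freqs Center frequencies (Hz).
#' @param fwhm Per-frequency envelope FWHM (s).
#' @return Array `[channel, frequency, time]` of power.
#' @export
morlet_tf <- function(x, rate, freqs, fwhm) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (any(freqs >= rate / 2)) stop("requested frequency above Nyquist")
  nch <- nrow(x); n <- ncol(x)
  pad <- ceiling(3 * max(fwhm) * rate)
  npad <- stats::nextn(n + 2L * pad, 2)
  xp <- matrix(0, nrow = npad, ncol = nch)
  xp[pad + seq_len(n), ] <- t(x)
  X <- stats::mvfft(xp)
  f <- (seq_len(npad) - 1L) * rate / npad
  pw <- array(0, dim = c(nch, length(freqs), n))
  half <- f <= rate / 2
  for (k in seq_along(freqs)) {
    sig_t <- fwhm[k] / (2 * sqrt(2 * log(2)))
    sig_f <- 1 / (2 * pi * sig_t)
    W <- numeric(npad)
    W[half] <- exp(-(f[half] - freqs[k])^2 / (2 * sig_f^2))
    Y <- stats::mvfft(X * W, inverse = TRUE) / npad
    pw[, k, ] <- t(Mod(Y[pad + seq_len(n), , drop = FALSE])^2)
  }
  pw
}

gait_grid_pct <- function(cfg = analysis_config()$eeg) {
  seq(cfg$gait_grid[1], cfg$gait_grid[2], by = cfg$gait_grid[3])
}

#' Resample a step epoch's TF power onto the gait grid
#'
#' Maps epoch time linearly so step onset is 0% and step completion 100%,
#' then interpolates power onto the grid (-30% to +130% in 0.5% increments,
#' 321 points); the buffers are filled from the epoch pads.
#'
#' @param pw Power array `[channel, frequency, time]` for one epoch.
#' @param epoch_t0 Time (s) of the first epoch sample.
#' @param rate Sampling rate (Hz).
#' @param start_s,end_s Step window (s).
#' @param grid_pct Gait grid (percent of step cycle).
#' @return Array `[channel, frequency, grid]`.
#' @export
resample_to_gait <- function(pw, epoch_t0, rate, start_s, end_s,
                             grid_pct = gait_grid_pct()) {
  nt <- dim(pw)[3]
  tt <- epoch_t0 + (seq_len(nt) - 1L) / rate
  target <- start_s + grid_pct / 100 * (end_s - start_s)
  if (any(target < tt[1] - 1e-9 | target > tt[nt] + 1e-9))
    stop("gait grid point outside epoch pads")
  # fractional indices for linear interpolation
  fi <- (target - tt[1]) * rate + 1
  lo <- pmin(pmax(floor(fi), 1L), nt - 1L)
  whi <- fi - lo
  out <- pw[, , lo, drop = FALSE] * rep(1 - whi, each = prod(dim(pw)[1:2])) +
    pw[, , lo + 1L, drop = FALSE] * rep(whi, each = prod(dim(pw)[1:2]))
  dim(out) <- c(dim(pw)[1:2], length(grid_pct))
  out
}

#' Percent-change normalization
#'
#' `100 * (P - B) / B` with the baseline `B` the mean over the full epoch
#' grid and all retained epochs, per channel x frequency. The output is
#' exactly mean-zero over the baseline region by construction.
#'
#' @param mean_pw Mean power array `[channel, frequency, grid]` over epochs.
#' @return Normalized array, same shape.
#' @export
percent_change <- function(mean_pw) {
  B <- apply(mean_pw, c(1, 2), mean)
  if (any(B <= 0)) stop("non-positive baseline power")
  100 * (mean_pw - as.vector(B)) / as.vector(B)
}

#' Gait-locked time-frequency analysis
#'
#' Step epoching, IQR outlier rejection, per-epoch Morlet transform,
#' resampling onto the gait grid, epoch averaging and percent-change
#' normalization, per participant.
#'
#' @param rec A preprocessed `eeg_recording`.
#' @param steps Step data.frame (start_s, end_s), typically from
#'   [extract_gait()] filtered to usable trials.
#' @param cfg `$eeg` config section.
#' @return List of class `gait_tf`: `power` (percent change, channel x
#'   frequency x grid), `grid_pct`, `freqs`, `channels`, `n_epochs`,
#'   `n_rejected`.
#' @export
gait_tf <- function(rec, steps, cfg = analysis_config()$eeg) {
  ep <- epoch_steps(rec, steps, pad = cfg$epoch_pad_s)
  ep <- reject_outlier_epochs(ep)
  g <- tf_grid(cfg)
  grid_pct <- gait_grid_pct(cfg)
  keep <- which(ep$keep)
  if (!length(keep)) stop("no step epochs retained")
  acc <- NULL
  for (i in keep) {
    pw <- morlet_tf(ep$epochs[[i]], ep$rate, g$freqs, g$fwhm)
    rs <- resample_to_gait(pw, ep$step$t0[i], ep$rate,
                           ep$step$start_s[i], ep$step$end_s[i], grid_pct)
    acc <- if (is.null(acc)) rs else acc + rs
  }
  mean_pw <- acc / length(keep)
  structure(list(power = percent_change(mean_pw), grid_pct = grid_pct,
                 freqs = g$freqs, channels = ep$channels,
                 n_epochs = length(keep), n_rejected = sum(!ep$keep)),
            class = "gait_tf")
}

#' Saccade-locked time-frequency analysis
#'
#' Epochs -600 to +1100 ms around each saccade onset, drops saccades whose
#' epoch starts before the containing trial's onset or runs past its end,
#' rejects outlier epochs by the IQR rule, computes Morlet power, labels each
#' epoch with the gait quartile of its step percentile (\[0,25) \[25,50)
#' \[50,75) \[75,100)), pools stance = Q1+Q4 and swing = Q2+Q3, and
#' normalizes every pool to percent change against the all-saccade baseline.
#'
#' @param rec A preprocessed `eeg_recording`.
#' @param saccades data.frame with onset_s and step_pct (step percentile of
#'   each saccade; NA rows are omitted and counted).
#' @param trial_windows data.frame trial_id, start_s, end_s.
#' @param cfg `$eeg` config section.
#' @return List of class `saccade_tf`: `time` (s), `freqs`, `pools` (named
#'   list stance/swing of channel x frequency x time percent-change arrays),
#'   `quartile` per epoch, counts of omitted epochs.
#' @export
saccade_locked_tf <- function(rec, saccades, trial_windows,
                              cfg = analysis_config()$eeg) {
  rate <- rec$rate
  win <- cfg$saccade_window_s
  chans <- setdiff(scalp_channels(rec), rec$bad_channels)
  n_unassigned <- sum(is.na(saccades$step_pct))
  sac <- saccades[!is.na(saccades$step_pct), , drop = FALSE]
  ok <- rep(FALSE, nrow(sac))
  for (i in seq_len(nrow(sac))) {
    tw <- trial_windows[trial_windows$start_s <= sac$onset_s[i] &
                          trial_windows$end_s > sac$onset_s[i], ]
    if (nrow(tw) == 1L && sac$onset_s[i] + win[1] >= tw$start_s &&
        sac$onset_s[i] + win[2] <= tw$end_s) ok[i] <- TRUE
  }
  n_outside <- sum(!ok)
  sac <- sac[ok, , drop = FALSE]
  if (!nrow(sac)) stop("no saccade epochs inside trials")
  w0 <- round(win[1] * rate); w1 <- round(win[2] * rate)
  epochs <- list(); quart <- integer(0)
  for (i in seq_len(nrow(sac))) {
    k <- round(sac$onset_s[i] * rate) + 1L
    if (k + w0 < 1L || k + w1 > ncol(rec$data)) next
    epochs[[length(epochs) + 1L]] <- rec$data[chans, (k + w0):(k + w1),
                                              drop = FALSE]
    quart <- c(quart, min(floor(sac$step_pct[i] / 25) + 1L, 4L))
  }
  sds <- vapply(epochs, sd, numeric(1))
  q <- quantile(sds, c(0.25, 0.75), names = FALSE); iqr <- q[2] - q[1]
  keep <- sds <= q[2] + 1.5 * iqr & sds >= q[1] - 1.5 * iqr
  g <- tf_grid(cfg)
  sums <- vector("list", 4L); counts <- integer(4L)
  all_sum <- NULL
  for (i in which(keep)) {
    pw <- morlet_tf(epochs[[i]], rate, g$freqs, g$fwhm)
    all_sum <- if (is.null(all_sum)) pw else all_sum + pw
    qq <- quart[i]
    sums[[qq]] <- if (is.null(sums[[qq]])) pw else sums[[qq]] + pw
    counts[qq] <- counts[qq] + 1L
  }
  n_kept <- sum(keep)
  base <- apply(all_sum / n_kept, c(1, 2), mean)  # all-saccade baseline
  norm_pool <- function(ids) {
    tot <- NULL; m <- 0L
    for (qq in ids) if (!is.null(sums[[qq]])) {
      tot <- if (is.null(tot)) sums[[qq]] else tot + sums[[qq]]
      m <- m + counts[qq]
    }
    if (is.null(tot) || m == 0L) return(NULL)
    100 * (tot / m - as.vector(base)) / as.vector(base)
  }
  structure(list(time = seq(w0, w1) / rate, freqs = g$freqs, channels = chans,
                 quartile = quart[keep],
                 pools = list(stance = norm_pool(c(1L, 4L)),
                              swing = norm_pool(c(2L, 3L))),
                 n_unassigned = n_unassigned, n_outside = n_outside,
                 n_rejected = sum(!keep)),
            class = "saccade_tf")
}
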