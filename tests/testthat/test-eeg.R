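test_that("re-referencing removes the common reference signal", {
  set.seed(11)
  n <- 3000; rate <- 300
  chans <- eeg_channels()
  base <- matrix(rnorm(21 * n), 21, n, dimnames = list(chans, NULL))
  # give channels shared structure so the correlation metric is happy
  shared <- rnorm(n)
  base[1:19, ] <- base[1:19, ] + rep(shared, each = 19)
  ref_sig <- sin(2 * pi * 7 * (1:n) / rate)
  withref <- base
  withref[1:19, ] <- withref[1:19, ] + rep(ref_sig, each = 19)
  withref["A1", ] <- ref_sig; withref["A2", ] <- ref_sig
  noref <- base
  noref["A1", ] <- 0; noref["A2", ] <- 0
  p1 <- preprocess_eeg(make_eeg(withref, rate))
  p2 <- preprocess_eeg(make_eeg(noref, rate))
  expect_equal(p1$data["Cz", ], p2$data["Cz", ], tolerance = 1e-6)

  nob <- base[setdiff(chans, "A1"), ]
  expect_error(preprocess_eeg(make_eeg(nob, rate)), "A1")
})

test_that("band-pass attenuates 50 Hz by more than 20 dB", {
  rate <- 300; n <- 6000
  chans <- eeg_channels()
  t <- (1:n) / rate
  sig50 <- sin(2 * pi * 50 * t)
  set.seed(12)
  data <- matrix(rnorm(21 * n, 0, 0.01), 21, n, dimnames = list(chans, NULL))
  shared <- rnorm(n)
  data[1:19, ] <- data[1:19, ] + rep(0.02 * shared + sig50, each = 19)
  data["A1", ] <- 0; data["A2", ] <- 0
  out <- preprocess_eeg(make_eeg(data, rate))
  p_in <- mean(sig50[1000:5000]^2)
  p_out <- mean(out$data["Cz", 1000:5000]^2)
  expect_gt(10 * log10(p_in / p_out), 20)
})

test_that("bad channels are flagged by deviation and correlation metrics", {
  set.seed(13)
  n <- 9000; rate <- 300
  chans <- eeg_channels()
  shared <- rnorm(n)
  data <- matrix(rnorm(21 * n, 0, 1), 21, n, dimnames = list(chans, NULL))
  data[1:19, ] <- data[1:19, ] + rep(shared * 1.5, each = 19)
  data["A1", ] <- rnorm(n, 0, 0.1); data["A2", ] <- rnorm(n, 0, 0.1)
  data["T8", ] <- rnorm(n, 0, 100)       # deviation outlier, uncorrelated too
  out <- preprocess_eeg(make_eeg(data, rate))
  expect_true("T8" %in% out$bad_channels)
  expect_false("Cz" %in% out$bad_channels)
})

test_that("trial epoching baseline-corrects and drops edge trials", {
  rate <- 300
  n <- rate * 20
  chans <- eeg_channels()
  data <- matrix(5, 21, n, dimnames = list(chans, NULL))  # constant offset
  rec <- make_eeg(data, rate)
  ep <- epoch_trials(rec, onsets = c(0.05, 2, 8), window = c(-0.1, 6.5))
  expect_equal(ep$n_dropped, 1L)              # first onset: epoch underflows
  expect_equal(length(ep$epochs), 2L)
  expect_true(all(abs(ep$epochs[[1]]) < 1e-12))
})

test_that("IQR epoch rejection keeps identical epochs, drops the outlier", {
  ep <- list(sd = rep(1, 100))
  expect_true(all(reject_outlier_epochs(ep)$keep))
  ep2 <- list(sd = c(rep(1, 99), 10))
  k <- reject_outlier_epochs(ep2)$keep
  expect_equal(sum(!k), 1L)
  expect_false(k[100])
})

test_that("morlet wavelets have the stated FWHM and flat sinusoid response", {
  g <- tf_grid()
  expect_equal(length(g$freqs), 50L)
  expect_equal(g$freqs[1], 3); expect_equal(g$freqs[50], 40)
  expect_equal(g$fwhm[1], 0.6); expect_equal(g$fwhm[50], 0.1)

  rate <- 300
  # FWHM of the 3-Hz wavelet's amplitude envelope via the impulse response
  x <- numeric(3001); x[1501] <- 1
  pw <- morlet_tf(x, rate, 3, 0.6)
  env <- sqrt(pw[1, 1, ])
  fwhm_meas <- sum(env >= max(env) / 2) / rate
  expect_lt(abs(fwhm_meas - 0.6) / 0.6, 0.05)

  # unit sinusoid: equal peak power (0.25) at every grid frequency
  t <- seq(0, 8, by = 1 / rate)
  peaks <- vapply(seq(1, 50, by = 7), function(k) {
    pw <- morlet_tf(sin(2 * pi * g$freqs[k] * t), rate, g$freqs[k], g$fwhm[k])
    mean(pw[1, 1, 1000:1400])
  }, numeric(1))
  expect_lt((max(peaks) - min(peaks)) / mean(peaks), 0.03)
  expect_equal(mean(peaks), 0.25, tolerance = 0.01)

  # a 10-Hz tone peaks at the grid frequency nearest 10 Hz
  pw10 <- morlet_tf(sin(2 * pi * 10 * t), rate, g$freqs, g$fwhm)
  prof <- apply(pw10[1, , 800:1600], 1, mean)
  expect_equal(which.max(prof), which.min(abs(g$freqs - 10)))
  expect_error(morlet_tf(sin(t), 100, c(10, 60), c(0.2, 0.2)), "Nyquist")

  # white noise: per-frequency mean power scales with wavelet bandwidth
  set.seed(14)
  pwn <- morlet_tf(rnorm(36000), rate, g$freqs, g$fwhm)
  mp <- apply(pwn[1, , 2000:34000], 1, mean)
  sig_f <- 1 / (2 * pi * g$fwhm / (2 * sqrt(2 * log(2))))
  ratio <- mp / sig_f
  expect_lt(sd(ratio) / mean(ratio), 0.1)
})

test_that("gait resampling maps the step linearly onto the grid", {
  rate <- 300
  nt <- 700
  t0 <- 0
  pw <- array(0, dim = c(2, 3, nt))
  tt <- t0 + (seq_len(nt) - 1) / rate
  for (ch in 1:2) for (f in 1:3) pw[ch, f, ] <- tt  # power linear in time
  rs <- resample_to_gait(pw, t0, rate, start_s = 0.7, end_s = 1.6)
  grid <- gait_grid_pct()
  expect_equal(length(grid), 321L)
  expect_equal(rs[1, 1, ], 0.7 + grid / 100 * 0.9, tolerance = 1e-9)
  expect_equal(rs[2, 3, grid == 0], 0.7, tolerance = 1e-9)
  expect_equal(rs[1, 2, grid == 100], 1.6, tolerance = 1e-9)
  expect_error(resample_to_gait(pw, t0, rate, start_s = 0.1, end_s = 2.2),
               "outside")
})

test_that("percent change is exact and mean-zero by construction", {
  m <- array(3, dim = c(2, 2, 10))
  expect_equal(percent_change(m), array(0, dim = c(2, 2, 10)))
  m2 <- array(rep(c(2, 0), each = 1, times = 20), dim = c(2, 2, 10))
  # channel 1 alternates? construct explicitly: half samples 2c, half 0
  m3 <- array(0, dim = c(1, 1, 10)); m3[1, 1, 1:5] <- 2
  out <- percent_change(m3)
  expect_equal(sort(unique(round(as.vector(out), 9))), c(-100, 100))
  set.seed(15)
  m4 <- array(runif(4 * 5 * 50, 1, 2), dim = c(4, 5, 50))
  out4 <- percent_change(m4)
  expect_equal(apply(out4, c(1, 2), mean),
               matrix(0, 4, 5), tolerance = 1e-10)
  expect_error(percent_change(array(0, dim = c(1, 1, 4))), "baseline")
})

test_that("injected gait-band modulation is recovered at the right phase", {
  w <- simulate_walk(walk_params("natural", n_trials = 12), seed = 41)
  e <- simulate_eeg(w, NULL, eeg_params(gait_mod_depth = 0.5,
                                        gait_band = c(8, 12),
                                        gait_mod_phase = pi), seed = 42)
  rec <- preprocess_eeg(e)
  gait <- extract_gait(make_walk_recording(w))
  gt <- gait_tf(rec, gait$steps[gait$steps$ok, ])
  m <- apply(gt$power, c(2, 3), mean)
  core <- gt$grid_pct >= 0 & gt$grid_pct < 100
  pk <- which(m[, core] == max(m[, core]), arr.ind = TRUE)
  expect_lt(abs(gt$freqs[pk[1]] - 10), 3)
  expect_lt(abs(gt$grid_pct[core][pk[2]] - 50), 10)
})

test_that("saccade-locked pooling follows the quartile convention", {
  w <- simulate_walk(walk_params("natural", n_trials = 8), seed = 43)
  g <- simulate_gaze(w, saccade_params(base_rate = 2), seed = 44)
  e <- simulate_eeg(w, g$saccades, eeg_params(), seed = 45)
  rec <- preprocess_eeg(e)
  tw <- data.frame(trial_id = w$truth$trials$trial_id,
                   start_s = w$truth$trials$start,
                   end_s = w$truth$trials$end)
  sac <- data.frame(onset_s = g$saccades$onset_s,
                    step_pct = g$saccades$step_pct)
  sl <- saccade_locked_tf(rec, sac, tw)
  expect_equal(names(sl$pools), c("stance", "swing"))
  expect_equal(dim(sl$pools$stance)[2], 50L)
  expect_equal(length(sl$time), round(1.7 * 300) + 1L)
  # quartile mapping: percentile 10 -> Q1 (stance); 60 -> Q3 (swing)
  expect_equal(min(floor(10 / 25) + 1, 4), 1)
  expect_true(all(sl$quartile %in% 1:4))
})
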