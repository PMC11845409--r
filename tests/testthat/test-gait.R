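test_that("troughs of a noiseless cosine are found at the analytic minima", {
  rate <- 90
  t <- seq(0, 5 - 1 / rate, by = 1 / rate)
  period <- 0.72
  z <- 1.7 - 0.02 * cos(2 * pi * (t + period / 2) / period)  # minima interior
  res <- detect_troughs(z, t, rate)
  true_minima <- seq(period / 2, 5, by = period)
  true_minima <- true_minima[true_minima > 0.2 & true_minima < 4.8]
  for (m in true_minima)
    expect_lt(min(abs(res$trough_times - m)), 1 / rate + 1e-9)
  expect_true(res$usable)

  # additive white noise, amplitude SNR 10: same count; the in-band noise
  # that survives the 6-Hz low-pass physically shifts the minima, so demand
  # sub-sample agreement for the bulk and 1.5 samples worst-case
  set.seed(4)
  amp_sd <- sd(z - mean(z))
  zn <- z + rnorm(length(z), 0, amp_sd / 10)
  resn <- detect_troughs(zn, t, rate)
  expect_equal(length(resn$trough_times), length(res$trough_times))
  dev <- abs(resn$trough_times - res$trough_times) * rate
  expect_gte(mean(dev <= 1), 0.9)
  expect_true(all(dev <= 1.5))
})

test_that("flat traces and short trials are handled", {
  rate <- 90
  t <- seq(0, 5 - 1 / rate, by = 1 / rate)
  res <- detect_troughs(rep(1.7, length(t)), t, rate)
  expect_false(res$usable)
  expect_equal(length(res$trough_times), 0L)
  expect_error(detect_troughs(rep(1.7, 30), (0:29) / rate, rate),
               "shorter than 1 s")
})

test_that("stride building follows both conventions and flag propagation", {
  steps <- structure(list(
    troughs = data.frame(trial_id = 1L, time = c(0, 0.7, 1.4, 2.1, 2.8)),
    steps = data.frame(trial_id = 1L, start_s = c(0, 0.7, 1.4, 2.1),
                       end_s = c(0.7, 1.4, 2.1, 2.8),
                       duration_s = rep(0.7, 4), ok = rep(TRUE, 4)),
    trials = data.frame(trial_id = 1L, usable = TRUE, reason = NA)),
    class = "step_table")
  expect_equal(nrow(build_strides(steps, "one-step-overlap")), 3L)
  expect_equal(nrow(build_strides(steps, "disjoint")), 2L)
  steps$steps$ok[2] <- FALSE   # flagged step removes the strides containing it
  s <- build_strides(steps, "one-step-overlap")
  expect_equal(nrow(s), 1L)
  expect_equal(s$start_s, 2.1 - 0.7)
})

test_that("stride resampling is linear-exact and keeps the two-minima shape", {
  t <- seq(0, 2, by = 1 / 90)
  y <- 3 * t + 1
  r <- resample_stride(t, y, 0.2, 1.8, n = 200L)
  expect_equal(r, seq(3 * 0.2 + 1, 3 * 1.8 + 1, length.out = 200),
               tolerance = 1e-9)
  expect_error(resample_stride(t, y, -0.5, 1), "outside")

  # one cosine cycle per step -> two minima per stride, at ~0% and ~50%
  step <- 0.6
  y2 <- -cos(2 * pi * t / step)
  r2 <- resample_stride(t, y2, step, step * 3, n = 200L)
  mins <- which(diff(sign(diff(r2))) > 0) + 1L
  expect_equal(length(mins), 1L)              # interior minimum at mid-stride
  expect_lt(abs(mins - 100), 3)
  expect_lt(abs(r2[1] - min(r2)), 1e-6)       # endpoints at the trough value

  # averaging strides of jittered durations retains the shape
  set.seed(5)
  acc <- rep(0, 200)
  for (i in 1:50) {
    d1 <- runif(1, 0.55, 0.85); d2 <- runif(1, 0.55, 0.85)
    tt <- seq(0, d1 + d2 + 2 / 90, by = 1 / 90)
    u <- ifelse(tt < d1, tt / d1, 1 + (tt - d1) / d2)
    acc <- acc + resample_stride(tt, -cos(2 * pi * u), 0, d1 + d2, 200L)
  }
  avg <- acc / 50
  mins <- which(diff(sign(diff(avg))) > 0) + 1L
  expect_equal(length(mins), 1L)
  expect_lt(abs(mins - 100), 4)
})

test_that("phase assignment is linear, overlap-aware and drops outsiders", {
  strides <- structure(
    data.frame(trial_id = 1L, start_s = c(0, 1.2), mid_s = c(1.2, 2.4),
               end_s = c(2.4, 3.6)),
    class = c("stride_segmentation", "data.frame"))
  ph <- assign_phase(c(0, 1.2, 5.0), strides)
  expect_equal(attr(ph, "n_dropped"), 1L)
  # t = 0: only the first stride contains it, percentile 0
  expect_equal(ph$pct[ph$event_time == 0], 0)
  # t = 1.2 is the mid trough of stride 1 (pct 50) and start of stride 2 (0)
  p12 <- sort(ph$pct[ph$event_time == 1.2])
  expect_equal(p12, c(0, 50))
  # step percentile resets at the mid trough
  expect_equal(ph$step_pct[ph$event_time == 1.2 & ph$stride_idx == 1], 0)

  # percentiles are invariant to uniform time rescaling
  strides2 <- strides; strides2[, c("start_s", "mid_s", "end_s")] <-
    strides[, c("start_s", "mid_s", "end_s")] * 3
  ph2 <- assign_phase(c(0, 3.6) , strides2)
  expect_equal(sort(ph2$pct), sort(ph$pct[ph$event_time %in% c(0, 1.2)]))
})

test_that("uniform events over a simulated walk give uniform percentiles", {
  w <- simulate_walk(walk_params("natural", n_trials = 60), seed = 31)
  rec <- make_walk_recording(w)
  strides <- build_strides(extract_gait(rec))
  set.seed(6)
  ev <- runif(4000, 0, max(w$tracking$time_s))
  ph <- assign_phase(ev, strides)
  expect_gt(nrow(ph), 2000)
  counts <- tabulate(floor(ph$pct / 2.5) + 1L, 40)
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("assigned percentiles agree with generator truth", {
  w <- simulate_walk(walk_params("slow", n_trials = 40), seed = 32)
  g <- simulate_gaze(w, saccade_params(modulation_depth = 0.3), seed = 33)
  rec <- make_recording(w, g)
  strides <- build_strides(extract_gait(rec))
  ph <- assign_phase(g$saccades$onset_s, strides)
  truth <- g$saccades
  m <- merge(ph, truth, by.x = "event_time", by.y = "onset_s")
  # the step percentile is unambiguous under the overlap convention: both
  # the assignment and the generator are linear in time within one step
  dd <- abs(m$step_pct.x - m$step_pct.y)
  dd <- pmin(dd, 100 - dd)                   # wrap at step boundaries
  expect_gt(mean(dd <= 2), 0.99)
})

test_that("automated exclusions catch dropouts and bad durations", {
  w <- simulate_walk(walk_params("slow", n_trials = 3), seed = 34)
  rec <- make_walk_recording(w)
  gait <- extract_gait(rec)
  tw <- data.frame(trial_id = w$truth$trials$trial_id,
                   start_s = w$truth$trials$start,
                   end_s = w$truth$trials$end)
  ex0 <- exclude_bad_trials(gait, NULL, trial_windows = tw)
  expect_false(any(ex0$excluded))

  drops <- data.frame(start_s = tw$start_s[2] + 1,
                      end_s = tw$start_s[2] + 1.5)
  ex1 <- exclude_bad_trials(gait, drops, trial_windows = tw)
  expect_true(ex1$excluded[ex1$trial_id == 2])
  expect_equal(ex1$reason[ex1$trial_id == 2], "dropout")

  # every second step out of bounds -> duration-bounds exclusion
  gait2 <- gait
  bad <- gait2$steps$trial_id == 3 &
    seq_len(nrow(gait2$steps)) %% 2 == 0
  gait2$steps$ok[gait2$steps$trial_id == 3] <-
    rep(c(TRUE, FALSE), length.out = sum(gait2$steps$trial_id == 3))
  ex2 <- exclude_bad_trials(gait2, NULL, trial_windows = tw)
  expect_true(ex2$excluded[ex2$trial_id == 3])
  expect_equal(ex2$reason[ex2$trial_id == 3], "duration bounds")
})
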