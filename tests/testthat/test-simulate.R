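test_that("simulated step durations match the condition statistics", {
  w <- simulate_walk(walk_params("slow", n_trials = 100), seed = 1)
  expect_gt(length(w$truth$step_durations), 300)
  expect_lt(abs(mean(w$truth$step_durations) - 0.72), 0.02)
  expect_lt(abs(sd(w$truth$step_durations) - 0.09), 0.03)

  wn <- simulate_walk(walk_params("natural", n_trials = 100), seed = 2)
  # ~ trial_duration / step_duration steps per 5-s trial
  steps_per_trial <- nrow(wn$truth$trough_times) / 100
  expect_lt(abs(steps_per_trial - 5 / 0.61), 1)
})

test_that("sd = 0 gives a perfectly periodic trajectory", {
  w <- simulate_walk(walk_params("slow", step_duration_sd = 0, n_trials = 3),
                     seed = 1)
  spacing <- unlist(tapply(w$truth$trough_times$time,
                           w$truth$trough_times$trial_id, diff))
  expect_equal(unname(spacing), rep(0.72, length(spacing)), tolerance = 1e-9)
  # troughs of the trajectory coincide with recorded trough times
  tr1 <- w$tracking[w$tracking$trial_id == 1, ]
  mins <- tr1$time_s[which(diff(sign(diff(tr1$head_z))) > 0) + 1L]
  tt <- w$truth$trough_times$time[w$truth$trough_times$trial_id == 1]
  for (x in tt) expect_lt(min(abs(mins - x)), 1 / 90 + 1e-9)
})

test_that("static condition is flat with no troughs", {
  w <- simulate_walk(walk_params("static", n_trials = 2), seed = 1)
  expect_equal(nrow(w$truth$trough_times), 0L)
  expect_equal(sd(w$tracking$head_z), 0)
  expect_error(simulate_walk(walk_params("slow", trial_duration = 0.2,
                                         n_trials = 1)),
               "shorter than a single step")
})

test_that("unmodulated saccade percentiles are uniform; m = 1 peaks at 0/50", {
  w <- simulate_walk(walk_params("natural", n_trials = 100), seed = 3)
  g <- simulate_gaze(w, saccade_params(base_rate = 10, modulation_depth = 0),
                     seed = 4)
  pct <- g$saccades$stride_pct
  expect_gt(length(pct), 2000)
  counts <- tabulate(floor(pct / 2.5) + 1L, 40)
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)

  g1 <- simulate_gaze(w, saccade_params(base_rate = 6, modulation_depth = 1,
                                        modulation_phase = 0), seed = 5)
  cnt <- tabulate(floor(g1$saccades$stride_pct / 2.5) + 1L, 40)
  # rate maxima at stride percentiles 0 and 50 (bins 1 and 21)
  expect_true(which.max(cnt) %in% c(1L, 2L, 20L, 21L, 22L, 40L))
  top <- order(cnt, decreasing = TRUE)[1:6]
  expect_true(any(top %in% c(1L, 40L)) && any(top %in% 20:22))
})

test_that("saccade count is conserved at lambda0 * walking time", {
  w <- simulate_walk(walk_params("natural", n_trials = 100), seed = 6)
  for (m in c(0, 0.5)) {
    g <- simulate_gaze(w, saccade_params(base_rate = 1.5,
                                         modulation_depth = m), seed = 7)
    expected <- 1.5 * 100 * 5
    # refractory thinning removes ~lambda0 * 0.12 of candidates
    expected_thinned <- expected / (1 + 1.5 * 0.12)
    expect_lt(abs(nrow(g$saccades) - expected_thinned),
              3 * sqrt(expected))
  }
  expect_error(saccade_params(modulation_depth = 1.2), "modulation_depth")
})

test_that("eeg generator validates its band and modulates power by phase", {
  expect_error(eeg_params(gait_band = c(2, 10)), "gait_band")
  expect_error(eeg_params(gait_band = c(10, 45)), "gait_band")
  w <- simulate_walk(walk_params("natural", n_trials = 20), seed = 8)
  e <- simulate_eeg(w, NULL, eeg_params(gait_mod_depth = 0.5,
                                        gait_band = c(8, 12),
                                        gait_mod_phase = pi), seed = 9)
  # oracle from the truth table: band power binned by true step percentile
  x <- e$data["Cz", ]
  ph <- stridesync:::true_phases(w$truth, e$time)
  band <- stridesync:::fft_filter(x, e$rate, low = 8, high = 12, order = 8L)
  pow <- band^2
  ok <- !is.na(ph$step_pct)
  bins <- floor(ph$step_pct[ok] / 10) + 1L
  prof <- tapply(pow[ok], bins, mean)
  # injected phase pi -> envelope peak at 50% of the step cycle
  expect_equal(unname(which.max(prof)), 6L, tolerance = 1)
})

test_that("generators are seed-deterministic", {
  w1 <- simulate_walk(walk_params("slow", n_trials = 3), seed = 10)
  w2 <- simulate_walk(walk_params("slow", n_trials = 3), seed = 10)
  expect_identical(w1$tracking, w2$tracking)
  g1 <- simulate_gaze(w1, saccade_params(), seed = 11)
  g2 <- simulate_gaze(w2, saccade_params(), seed = 11)
  expect_identical(g1$gaze, g2$gaze)
  expect_identical(g1$saccades, g2$saccades)
  e1 <- simulate_eeg(w1, g1$saccades, eeg_params(), seed = 12)
  e2 <- simulate_eeg(w2, g2$saccades, eeg_params(), seed = 12)
  expect_identical(e1$data, e2$data)
})

test_that("noiseless walks are recovered exactly by gait extraction", {
  # truth-consistency invariant: troughs recovered within one sample
  w <- simulate_walk(walk_params("natural", n_trials = 10), seed = 13)
  rec <- make_walk_recording(w)
  gait <- extract_gait(rec)
  tol <- 1 / 90 + 1e-9
  tt <- w$truth$trough_times
  interior <- mapply(function(tm, tr) {
    tw <- w$truth$trials[w$truth$trials$trial_id == tr, ]
    tm - tw$start > 0.2 && tw$end - tm > 0.2
  }, tt$time, tt$trial_id)
  hits <- vapply(tt$time[interior], function(x)
    min(abs(gait$troughs$time - x)) <= tol, logical(1))
  expect_true(all(hits))
  expect_lt(abs(mean(gait$steps$duration_s) -
                  mean(w$truth$step_durations)) /
              mean(w$truth$step_durations), 0.01)
})
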