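constant_recording <- function(n = 900, rate = 90) {
  structure(
    data.table::data.table(
      time_s = (seq_len(n) - 1L) / rate, head_x = 0, head_y = 0,
      head_z = 1.7, gaze_origin_x = 0, gaze_origin_y = 0, gaze_origin_z = 1.7,
      gaze_dir_x = 0, gaze_dir_y = 0, gaze_dir_z = 1,
      trial_id = 1L),
    class = c("gh_recording", "data.table", "data.frame"), rate = rate)
}

test_that("blink detection flags jumps and merges close intervals", {
  rec <- constant_recording()
  expect_equal(nrow(detect_blinks(rec)), 0L)
  expect_error(detect_blinks(rec[0, ]), "empty")

  r1 <- data.table::copy(rec)
  r1$gaze_origin_y[100] <- r1$gaze_origin_y[100] + 1.0  # single-frame jump
  b <- detect_blinks(r1)
  expect_equal(nrow(b), 1L)
  expect_true(b$start_s <= r1$time_s[99] && b$end_s >= r1$time_s[101])
  expect_equal(b$interp_start_s, b$start_s - 0.1)
  expect_equal(b$interp_end_s, b$end_s + 0.1)

  # three dropouts >= 150 ms apart stay separate, each with 100-ms margins
  r3 <- data.table::copy(rec)
  for (k in c(100, 300, 500)) r3$gaze_origin_y[k:(k + 5)] <-
      r3$gaze_origin_y[k:(k + 5)] + 1.0
  b3 <- detect_blinks(r3)
  expect_equal(nrow(b3), 3L)
  expect_equal(b3$interp_end_s - b3$end_s, rep(0.1, 3))

  # sub-criterion jump (0.5 m < 0.8 m) is not a blink
  r4 <- data.table::copy(rec)
  r4$gaze_origin_y[100] <- r4$gaze_origin_y[100] + 0.5
  expect_equal(nrow(detect_blinks(r4)), 0L)
})

test_that("blink interpolation is linear-exact and renormalizes gaze", {
  rate <- 90; n <- 900
  rec <- constant_recording(n, rate)
  ramp <- seq(0, 1, length.out = n)
  rec$gaze_origin_x <- ramp
  blinks <- data.frame(start_s = 2, end_s = 2.2,
                       interp_start_s = 1.9, interp_end_s = 2.3)
  out <- interpolate_blinks(rec, blinks)
  expect_equal(out$gaze_origin_x, ramp, tolerance = 1e-12)   # chord == ramp
  expect_equal(out$gaze_dir_z, rep(1, n))                    # constant intact

  # sinusoid: interpolated segment equals the chord between window endpoints
  rec2 <- constant_recording(n, rate)
  s <- sin(2 * pi * 1.3 * rec2$time_s)
  rec2$gaze_origin_y <- s
  out2 <- interpolate_blinks(rec2, blinks)
  t <- rec2$time_s
  inside <- which(t >= 1.9 & t <= 2.3)
  lo <- min(inside) - 1L; hi <- max(inside) + 1L
  chord <- approx(t[c(lo, hi)], s[c(lo, hi)], xout = t[inside])$y
  expect_equal(out2$gaze_origin_y[inside], chord, tolerance = 1e-12)
  expect_equal(out2$gaze_origin_y[-inside], s[-inside])

  expect_warning(
    interpolate_blinks(rec, data.frame(start_s = 0, end_s = 0.05,
                                       interp_start_s = -0.1,
                                       interp_end_s = 0.15)),
    "clamped")
})

test_that("gaze-angle mapping matches its construction and inverts", {
  rec <- constant_recording(10)
  a <- gaze_to_angles(rec)
  expect_equal(a$azimuth_deg, rep(0, 10))
  expect_equal(a$elevation_deg, rep(0, 10))

  rec$gaze_dir_x <- sin(5 * pi / 180)
  rec$gaze_dir_z <- cos(5 * pi / 180)
  a5 <- gaze_to_angles(rec)
  expect_equal(a5$azimuth_deg, rep(5, 10), tolerance = 1e-12)

  set.seed(1)
  v <- matrix(rnorm(300), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v <- v[v[, 3] > 0.1, ]                       # forward hemisphere
  rec2 <- constant_recording(nrow(v))
  rec2$gaze_dir_x <- v[, 1]; rec2$gaze_dir_y <- v[, 2]; rec2$gaze_dir_z <- v[, 3]
  ang <- gaze_to_angles(rec2)
  back <- angles_to_gaze(ang$azimuth_deg, ang$elevation_deg)
  expect_equal(unname(back), unname(v), tolerance = 1e-9)
})

test_that("smoothed velocity behaves on ramps, constants and noise", {
  rate <- 90; n <- 500
  t <- (seq_len(n) - 1) / rate
  a <- data.frame(azimuth_deg = 10 * t, elevation_deg = rep(0, n))
  v <- compute_smoothed_velocity(a, rate, 5L)
  expect_equal(v$vx[10:(n - 10)], rep(10, n - 19), tolerance = 1e-9)
  expect_equal(v$vy, rep(0, n))
  expect_equal(nrow(v), n)
  expect_error(compute_smoothed_velocity(a, rate, 4L), "odd")

  set.seed(2)
  aw <- data.frame(azimuth_deg = rnorm(20000), elevation_deg = 0)
  vraw <- compute_smoothed_velocity(aw, rate, 1L)
  vsm <- compute_smoothed_velocity(aw, rate, 5L)
  # 5-sample average of a telescoping difference: var ratio ~ 1/5 is only a
  # heuristic for white noise; telescoped first differences give 2/25 of the
  # two-sample variance (independent oracle below)
  ratio <- var(vsm$vx[10:19990]) / var(vraw$vx[10:19990])
  # oracle: mean of 5 consecutive backward differences of white noise is
  # (x[k+2] - x[k-3]) / 5, so var = 2 sigma^2 rate^2 / 25 vs 2 sigma^2 rate^2
  expect_equal(ratio, 1 / 25, tolerance = 0.05)
})

test_that("threshold estimator matches closed forms and scales", {
  v <- data.frame(vx = rep(c(-1, 0, 1), 10), vy = rep(c(-2, 0, 2), 10))
  eta <- estimate_thresholds(v, 6)
  expect_equal(unname(eta["eta_x"]), 6)        # sqrt(median 1 - 0) * 6
  expect_equal(unname(eta["eta_y"]), 12)
  eta3 <- estimate_thresholds(v * 3.5, 6)
  expect_equal(unname(eta3), unname(eta) * 3.5)
  expect_error(estimate_thresholds(data.frame(vx = rep(1, 20),
                                              vy = rep(c(-1, 1), 10)), 6,
                                   trial = 7),
               "trial 7")

  # Monte-Carlo oracle: for N(0,1), sigma_med = sqrt(qchisq(0.5, 1)) = 0.6745
  set.seed(3)
  vg <- data.frame(vx = rnorm(1e5), vy = rnorm(1e5))
  etag <- estimate_thresholds(vg, 6)
  expect_equal(unname(etag["eta_x"]), 6 * sqrt(qchisq(0.5, 1)),
               tolerance = 0.02)
})

test_that("saccade detection applies run-length, ellipse and blink rules", {
  n <- 200; rate <- 90
  time <- (seq_len(n) - 1) / rate
  v <- data.frame(vx = rep(0, n), vy = rep(0, n))
  eta <- c(eta_x = 10, eta_y = 10)
  expect_equal(nrow(detect_saccades(v, eta, time)), 0L)

  v1 <- v; v1$vx[50] <- 100                       # single sample: rejected
  expect_equal(nrow(detect_saccades(v1, eta, time, min_samples = 2L)), 0L)

  v3 <- v; v3$vx[50:52] <- 100                    # 3-sample event
  ev <- detect_saccades(v3, eta, time, min_samples = 2L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_idx, 50L)
  expect_equal(ev$duration_s, 3 / rate)
  expect_equal(ev$peak_vel, 100)

  # ellipse: both axes at 0.8 * eta crosses jointly (0.64 + 0.64 > 1)
  v4 <- v; v4$vx[50:52] <- 8; v4$vy[50:52] <- 8
  expect_equal(nrow(detect_saccades(v4, eta, time)), 1L)
  v5 <- v; v5$vx[50:52] <- 8
  expect_equal(nrow(detect_saccades(v5, eta, time)), 0L)

  # events adjacent to blink-interpolated samples are discarded
  mask <- rep(FALSE, n); mask[53] <- TRUE
  expect_equal(nrow(detect_saccades(v3, eta, time, blink_mask = mask)), 0L)
})

test_that("detection is invariant to a common scaling of the angles", {
  w <- simulate_walk(walk_params("slow", n_trials = 5), seed = 21)
  g <- simulate_gaze(w, saccade_params(), seed = 22)
  rec <- make_recording(w, g)
  base <- detect_saccades_recording(rec)
  # scale gaze angles by ~3: tangent-plane scaling of direction components
  ang <- gaze_to_angles(rec)
  big <- angles_to_gaze(3 * ang$azimuth_deg, 3 * ang$elevation_deg)
  rec2 <- data.table::copy(rec)
  rec2$gaze_dir_x <- big[, 1]; rec2$gaze_dir_y <- big[, 2]
  rec2$gaze_dir_z <- big[, 3]
  scaled <- detect_saccades_recording(rec2)
  expect_equal(scaled$onset_s, base$onset_s, tolerance = 1 / 90)
})

test_that("fixation noise alone yields under one event per 10 s", {
  w <- simulate_walk(walk_params("slow", n_trials = 20), seed = 23)
  g <- simulate_gaze(w, saccade_params(base_rate = 0, blink_rate = 0),
                     seed = 24)
  rec <- make_recording(w, g)
  sacc <- detect_saccades_recording(rec)
  expect_lte(nrow(sacc), 20 * 5 / 10)
})

test_that("detector meets recall/precision bounds on synthetic sessions", {
  w <- simulate_walk(walk_params("slow", n_trials = 30), seed = 25)
  g <- simulate_gaze(w, saccade_params(modulation_depth = 0), seed = 26)
  rec <- make_recording(w, g)
  sacc <- detect_saccades_recording(rec)
  m <- match_events(sacc$onset_s, g$saccades$onset_s, 1 / 90 + 1e-9)
  expect_gte(m["recall"], 0.95)
  expect_gte(m["precision"], 0.95)
})
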