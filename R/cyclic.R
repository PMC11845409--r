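#' Bin stride percentiles
#'
#' Counts events in 40 equal half-open bins \[2.5k, 2.5(k+1)) of stride
#' completion (zero overlap). Optionally expressed as relative change from
#' the participant mean, `(c_i - mean(c)) / mean(c)`, which sums to zero.
#'
#' @param percentiles Event stride percentiles in \[0, 100).
#' @param n_bins Number of bins (default 40).
#' @param normalize "raw" counts or "relative" change from the mean.
#' @return List of class `binned_phase`: `centers`, `values`,
#'   `normalization`.
#' @export
bin_phases <- function(percentiles, n_bins = 40L,
                       normalize = c("raw", "relative")) {
  normalize <- match.arg(normalize)
  if (!length(percentiles)) stop("no events to bin")
  if (any(percentiles < 0 | percentiles >= 100))
    stop("percentiles must lie in [0, 100)")
  width <- 100 / n_bins
  idx <- floor(percentiles / width) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  values <- counts
  if (normalize == "relative") values <- (counts - mean(counts)) / mean(counts)
  structure(list(centers = (seq_len(n_bins) - 0.5) * width,
                 values = as.numeric(values), normalization = normalize),
            class = "binned_phase")
}

fourier_design <- function(x, w) {
  th <- 2 * pi * w * x / 100
  cbind(1, cos(th), sin(th))
}

#' First-order Fourier fit at a forced frequency
#'
#' Least squares of `f(x) = a0 + a1*cos(theta) + b1*sin(theta)`, `theta =
#' 2*pi*w*x/100`, at fixed frequency `w` (cycles per stride). Amplitude
#' `A = sqrt(a1^2 + b1^2)` and phase `phi = atan2(-b1, a1)` give the
#' equivalent form `a0 + A*cos(theta + phi)`. At fixed `w` the problem is
#' linear, so the solution is exact and deterministic.
#'
#' @param series A `binned_phase` or numeric vector of bin values.
#' @param w Frequency (cycles per stride).
#' @param centers Bin centers (percentile), required when `series` is a bare
#'   vector.
#' @return List of class `fourier_fit`: a0, a1, b1, A, phi, w, r2.
#' @export
fit_fourier <- function(series, w, centers = NULL) {
  if (inherits(series, "binned_phase")) {
    y <- series$values; x <- series$centers
  } else { y <- as.numeric(series); x <- centers }
  stopifnot(w > 0, length(y) == length(x))
  X <- fourier_design(x, w)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= 0) 0 else max(0, 1 - sum(fit$residuals^2) / sst)
  structure(list(a0 = cf[[1]], a1 = cf[[2]], b1 = cf[[3]],
                 A = sqrt(cf[[2]]^2 + cf[[3]]^2),
                 phi = atan2(-cf[[3]], cf[[2]]), w = w, r2 = r2),
            class = "fourier_fit")
}

# R^2 at every grid frequency for every column of Y (bins x m), vectorized.
# Precomputed projections make permutation scans cheap.
scan_r2_matrix <- function(Y, centers, grid) {
  Y <- as.matrix(Y)
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  out <- matrix(0, nrow = length(grid), ncol = ncol(Y))
  for (i in seq_along(grid)) {
    X <- fourier_design(centers, grid[i])
    B <- solve(crossprod(X), crossprod(X, Y))
    ssres <- colSums((Y - X %*% B)^2)
    r2 <- ifelse(sst > 0, 1 - ssres / sst, 0)
    out[i, ] <- pmax(0, r2)
  }
  out
}

#' Forced-frequency scan
#'
#' Fits the first-order Fourier model at every frequency of the grid
#' (default 0.2 to 10 cycles per stride in 0.2 steps, 50 values) and records
#' R^2; the best frequency maximizes R^2, ties broken toward the lower
#' frequency.
#'
#' @param series A `binned_phase` (typically the group mean of
#'   participant-normalized series).
#' @param grid Frequency grid (cycles per stride).
#' @return List of class `fourier_scan`: `grid`, `r2`, `best_freq`,
#'   `best_fit`.
#' @export
scan_frequencies <- function(series, grid = seq(0.2, 10, by = 0.2)) {
  stopifnot(length(grid) > 0)
  r2 <- drop(scan_r2_matrix(matrix(series$values, ncol = 1),
                            series$centers, grid))
  best <- which.max(r2)              # which.max returns the first maximum
  structure(list(grid = grid, r2 = r2, best_freq = grid[best],
                 best_fit = fit_fourier(series, grid[best])),
            class = "fourier_scan")
}

#' Permutation null for the frequency scan
#'
#' Each permutation shuffles bin labels independently within each
#' participant (sampling percentile values without replacement), recomputes
#' the group-mean series and reruns the full scan. The per-frequency 95th
#' percentile of permuted R^2 is the null upper bound.
#'
#' @param participant_series Matrix (bins x participants) of per-participant
#'   binned values, or a single participant's vector.
#' @param centers Bin centers.
#' @param grid Frequency grid.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed.
#' @param probs Null quantile (default 0.95).
#' @return List of class `permutation_null`: `bound` (per frequency),
#'   `r2_perm` (grid x n_perm), `n_perm`, `seed`.
#' @export
permutation_null <- function(participant_series, centers,
                             grid = seq(0.2, 10, by = 0.2),
                             n_perm = 1000L, seed = 1L, probs = 0.95) {
  S <- as.matrix(participant_series)
  if (n_perm < 100L) warning("fewer than 100 permutations: unstable bound")
  nb <- nrow(S); np <- ncol(S)
  Y <- with_seed(seed, {
    Y <- matrix(0, nrow = nb, ncol = n_perm)
    for (p in seq_len(n_perm)) {
      acc <- numeric(nb)
      for (j in seq_len(np)) acc <- acc + S[sample.int(nb), j]
      Y[, p] <- acc / np
    }
    Y
  })
  r2p <- scan_r2_matrix(Y, centers, grid)
  structure(list(bound = apply(r2p, 1, quantile, probs = probs, names = FALSE),
                 r2_perm = r2p, n_perm = n_perm, seed = seed),
            class = "permutation_null")
}

#' Entrainment significance decisions
#'
#' A frequency is significant when its observed R^2 strictly exceeds the
#' permutation bound; band-level significance (default 1.5-2.5 cycles per
#' stride) means any significant frequency inside the band.
#'
#' @param scan A `fourier_scan`.
#' @param null A `permutation_null` on the same grid.
#' @param band Two-element band (cycles per stride).
#' @return List: `sig` (per-frequency logical), `band_sig`, `band`.
#' @export
test_entrainment <- function(scan, null, band = c(1.5, 2.5)) {
  stopifnot(length(scan$r2) == length(null$bound))
  sig <- scan$r2 > null$bound
  in_band <- scan$grid >= band[1] & scan$grid <= band[2]
  list(sig = sig, band_sig = any(sig & in_band), band = band)
}

#' Participant-level entrainment test
#'
#' Runs the scan and the shuffling null for one participant's binned series
#' and reports band-level significance, mirroring the group procedure.
#'
#' @param series A `binned_phase` for one participant.
#' @param grid,n_perm,seed,band See [permutation_null()] and
#'   [test_entrainment()].
#' @return List: `scan`, `null`, `sig` decisions, `phase_at` function of
#'   frequency giving the fitted phase.
#' @export
participant_entrainment <- function(series, grid = seq(0.2, 10, by = 0.2),
                                    n_perm = 1000L, seed = 1L,
                                    band = c(1.5, 2.5)) {
  scan <- scan_frequencies(series, grid)
  null <- permutation_null(matrix(series$values, ncol = 1), series$centers,
                           grid, n_perm, seed)
  dec <- test_entrainment(scan, null, band)
  list(scan = scan, null = null, sig = dec,
       phase_at = function(w) fit_fourier(series, w)$phi)
}

#' Bayesian population prevalence
#'
#' Posterior for the population prevalence gamma of a within-participant
#' effect, from k significant tests out of n, with test false-positive rate
#' alpha and sensitivity beta: the probability a random participant tests
#' positive is `theta = gamma*beta + (1-gamma)*alpha`, so under a uniform
#' prior `p(gamma) ~ theta^k (1-theta)^(n-k)`. Reports the maximum a
#' posteriori estimate (cross-checked against the analytic mode
#' `clip((k/n - alpha)/(beta - alpha), 0, 1)`) and the 95% highest posterior
#' density interval found by density water-filling.
#'
#' @param k Number of significant participants.
#' @param n Number of participants.
#' @param alpha Test false-positive rate.
#' @param beta Test sensitivity (default 1).
#' @param grid_size Posterior grid resolution.
#' @param hpdi_mass HPDI mass (default 0.95).
#' @return List of class `prevalence_posterior`: k, n, alpha, beta, `gamma`
#'   grid, `density`, `map`, `map_analytic`, `hpdi` (lo, hi).
#' @export
prevalence <- function(k, n, alpha = 0.05, beta = 1, grid_size = 10001L,
                       hpdi_mass = 0.95) {
  assert_that(k >= 0 && k <= n, "k must lie in [0, n]")
  assert_that(alpha > 0 && alpha < beta && beta <= 1,
              "need 0 < alpha < beta <= 1")
  g <- seq(0, 1, length.out = grid_size)
  theta <- g * beta + (1 - g) * alpha
  logd <- k * log(theta)
  if (n > k) logd <- logd + (n - k) * log1p(-theta)  # avoid 0 * log(0)
  d <- exp(logd - max(logd))
  dx <- g[2] - g[1]
  d <- d / (sum(d) * dx)
  map_grid <- g[which.max(d)]
  map_analytic <- min(max((k / n - alpha) / (beta - alpha), 0), 1)
  ord <- order(d, decreasing = TRUE)
  cum <- cumsum(d[ord]) * dx
  in_hpdi <- ord[seq_len(which(cum >= hpdi_mass)[1])]
  structure(list(k = k, n = n, alpha = alpha, beta = beta,
                 gamma = g, density = d, map = map_grid,
                 map_analytic = map_analytic,
                 hpdi = c(lo = min(g[in_hpdi]), hi = max(g[in_hpdi]))),
            class = "prevalence_posterior")
}

#' @export
print.prevalence_posterior <- function(x, ...) {
  cat(sprintf("prevalence: k=%d/%d, alpha=%.3f, beta=%.2f -> MAP = %.2f, 95%% HPDI [%.2f, %.2f]\n",
              x$k, x$n, x$alpha, x$beta, x$map, x$hpdi["lo"], x$hpdi["hi"]))
  invisible(x)
}

#' Rayleigh test of circular non-uniformity
#'
#' Mean resultant length `Rbar = |mean(exp(i*phi))|`, `Z = n*Rbar^2`, with
#' the standard small-sample p approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (n*Rbar)^2)) - (1 + 2n))`.
#'
#' @param phases Phases in radians.
#' @return List of class `rayleigh_test`: n, Rbar, Z, p.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  stopifnot(n >= 3L)
  Rbar <- Mod(mean(exp(1i * phases)))
  Z <- n * Rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * Rbar)^2)) - (1 + 2 * n))
  structure(list(n = n, Rbar = Rbar, Z = Z, p = min(1, p)),
            class = "rayleigh_test")
}

#' Group-level entrainment analysis
#'
#' Convenience wrapper: builds the participant-normalized group-mean series,
#' runs the scan, the permutation null, the per-participant tests, the
#' prevalence estimate and the phase-clustering test.
#'
#' @param percentiles_by_participant List of numeric vectors of stride
#'   percentiles, one per participant.
#' @param cfg `$cyclic` section of an [analysis_config()].
#' @param seed Seed (split internally).
#' @param prevalence_alpha False-positive rate used for the prevalence
#'   computation (default from cfg).
#' @return List of class `entrainment_result`.
#' @export
group_entrainment <- function(percentiles_by_participant,
                              cfg = analysis_config()$cyclic, seed = 1L,
                              prevalence_alpha = cfg$prevalence_alpha) {
  np <- length(percentiles_by_participant)
  stopifnot(np >= 2L)
  binned <- lapply(percentiles_by_participant, bin_phases,
                   n_bins = cfg$n_bins, normalize = "relative")
  centers <- binned[[1]]$centers
  S <- vapply(binned, `[[`, numeric(cfg$n_bins), "values")
  group <- structure(list(centers = centers, values = rowMeans(S),
                          normalization = "relative"),
                     class = "binned_phase")
  seeds <- split_seed(seed, np + 1L)
  scan <- scan_frequencies(group, cfg$freq_grid)
  null <- permutation_null(S, centers, cfg$freq_grid, cfg$n_perm, seeds[1])
  group_sig <- test_entrainment(scan, null, cfg$band)
  per <- lapply(seq_len(np), function(j) {
    participant_entrainment(binned[[j]], cfg$freq_grid, cfg$n_perm,
                            seeds[j + 1L], cfg$band)
  })
  k <- sum(vapply(per, function(p) p$sig$band_sig, logical(1)))
  prev <- prevalence(k, np, alpha = prevalence_alpha,
                     beta = cfg$prevalence_beta)
  sig_idx <- which(vapply(per, function(p) p$sig$band_sig, logical(1)))
  phases <- vapply(sig_idx, function(j) per[[j]]$phase_at(2), numeric(1))
  ray <- if (length(phases) >= 3L) rayleigh_test(phases) else NULL
  structure(list(scan = scan, null = null, group_sig = group_sig,
                 participants = per, k = k, n = np, prevalence = prev,
                 phases = phases, rayleigh = ray),
            class = "entrainment_result")
}
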