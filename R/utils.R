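#' @useDynLib stridesync, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft median qt quantile rnorm runif rbinom sd var
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

# Deterministic child seeds: one top-level seed fans out to per-stage streams.
# Keeps every stage reproducible independently of how many draws earlier
# stages consumed. Values stay below 2^31 - 1.
split_seed <- function(seed, k = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) * 48271 + 1664525 * seq_len(k)) %% 2147483562L + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Zero-phase filtering by frequency-domain multiplication with a Butterworth
# magnitude response (order n), on a reflection-padded signal. No IIR state,
# no phase distortion; adequate for the gentle band edges used here.
butter_mag <- function(f, cutoff, order = 4L) {
  1 / sqrt(1 + (f / cutoff)^(2 * order))
}

fft_filter <- function(x, rate, low = NULL, high = NULL, order = 4L) {
  n <- length(x)
  if (n < 4L) return(x)
  pad <- min(n - 1L, max(32L, ceiling(rate)))  # ~1 s reflection padding
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  np <- length(xp)
  f <- c(seq_len(ceiling(np / 2)) - 1L, -rev(seq_len(floor(np / 2)))) * rate / np
  af <- abs(f)
  h <- rep(1, np)
  if (!is.null(high)) h <- h * butter_mag(af, high, order)
  if (!is.null(low)) {
    hp <- rep(0, np)
    pos <- af > 0
    hp[pos] <- 1 / sqrt(1 + (low / af[pos])^(2 * order))
    h <- h * hp
  }
  y <- Re(fft(fft(xp) * h, inverse = TRUE)) / np
  y[(pad + 1L):(pad + n)]
}

# Centered moving average with shrinking windows at the edges, so the output
# has the same length as the input.
moving_average <- function(x, window) {
  if (window %% 2L == 0L) stop("moving-average window must be odd")
  n <- length(x)
  if (n == 0L) return(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

linear_detrend <- function(x) {
  n <- length(x)
  if (n < 2L) return(x - mean(x))
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), x)
  x - fit$fitted.values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
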