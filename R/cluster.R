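#' Per-pixel one-sample t map
#'
#' One-sample t statistics (df = n - 1) of participant maps against zero;
#' for a paired contrast, pass the per-participant difference maps.
#' Zero-variance pixels get t = 0 with a warning.
#'
#' @param maps Matrix participants x pixels.
#' @return Numeric vector of t scores (length = pixels).
#' @export
t_map <- function(maps) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  stopifnot(n >= 3L)
  m <- colMeans(maps)
  v <- (colSums(maps^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- numeric(length(m))
  zero <- v == 0
  if (any(zero)) warning(sum(zero), " zero-variance pixel(s): t set to 0")
  t[!zero] <- m[!zero] / sqrt(v[!zero] / n)
  t
}

#' Threshold a t map into clusters
#'
#' Pixels exceeding the two-tailed critical value at `p_thresh` (default
#' 0.01) form same-sign connected components: 4-connectivity when the map is
#' a 2D grid (`dims` given), or graph connectivity when an adjacency list is
#' supplied. Each cluster's mass is the sum of its member t scores.
#'
#' @param t Numeric vector of t scores.
#' @param df Degrees of freedom.
#' @param p_thresh Cluster-forming p (two-tailed).
#' @param dims `c(nrow, ncol)` of the grid map (row-major pixel order along
#'   columns, as produced by flattening a matrix).
#' @param adjacency List of integer neighbour vectors (1-based), one per
#'   pixel, for non-grid maps.
#' @return data.frame of class `cluster_set`: cluster id, sign, mass, size,
#'   peak_idx; the pixel labels are in the `labels` attribute.
#' @export
threshold_clusters <- function(t, df, p_thresh = 0.01, dims = NULL,
                               adjacency = NULL) {
  stopifnot(df >= 2)
  crit <- qt(1 - p_thresh / 2, df)
  if (!is.null(dims)) {
    res <- grid_clusters_cpp(matrix(t, dims[1], dims[2]), crit)
  } else if (!is.null(adjacency)) {
    res <- graph_clusters_cpp(as.numeric(t), crit, adjacency)
  } else stop("supply dims (grid) or adjacency (graph)")
  mass <- res$mass
  labels <- res$labels
  sizes <- if (length(mass)) tabulate(as.vector(labels), nbins = length(mass))
           else integer(0)
  out <- data.frame(cluster = seq_along(mass),
                    sign = ifelse(mass >= 0, 1L, -1L),
                    mass = mass, size = sizes, peak_idx = res$peak_idx)
  structure(out, class = c("cluster_set", "data.frame"),
            labels = labels, crit = crit, df = df)
}

#' Cluster-level permutation p values
#'
#' Monte Carlo sign-flip permutation test (default 2000 repetitions): each
#' permutation flips the sign of every participant's whole map at random
#' (for a paired contrast on difference maps this is exactly the exchange of
#' condition labels within participant), recomputes the t map and records
#' the maximum |cluster mass|. `p_cluster = (1 + #{perm >= observed}) /
#' (n_perm + 1)`, a familywise-corrected p.
#'
#' @param maps Matrix participants x pixels (difference maps for paired
#'   contrasts).
#' @param clusters A `cluster_set` from [threshold_clusters()] on
#'   `t_map(maps)`.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @param dims,adjacency Connectivity, as in [threshold_clusters()].
#' @return The `cluster_set` with a `p_cluster` column; permutation maxima
#'   in the `null_max` attribute.
#' @export
permutation_cluster_p <- function(maps, clusters, n_perm = 2000L, seed = 1L,
                                  dims = NULL, adjacency = NULL) {
  if (n_perm < 500L) warning("fewer than 500 permutations: p unstable")
  maps <- as.matrix(maps)
  n <- nrow(maps)
  crit <- attr(clusters, "crit")
  sumsq <- colSums(maps^2)
  null_max <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    M <- crossprod(signs, maps) / n            # n_perm x npix means
    V <- sweep(-n * M^2, 2, sumsq, "+") / (n - 1)
    V[V < 1e-300] <- 1e-300
    Tm <- M / sqrt(V / n)
    vapply(seq_len(n_perm), function(p) {
      tp <- Tm[p, ]
      if (!is.null(dims)) grid_max_mass_cpp(matrix(tp, dims[1], dims[2]), crit)
      else graph_max_mass_cpp(tp, crit, adjacency)
    }, numeric(1))
  })
  obs <- abs(clusters$mass)
  clusters$p_cluster <- vapply(obs, function(m)
    (1 + sum(null_max >= m)) / (n_perm + 1), numeric(1))
  attr(clusters, "null_max") <- null_max
  clusters
}

#' Cluster test of a set of 2D maps against zero
#'
#' Convenience wrapper: t map, thresholding and permutation p values for
#' participants x (frequency x time/percentile) maps.
#'
#' @param maps Matrix participants x pixels, pixels flattened from an
#'   `nrow x ncol` map.
#' @param dims Map dimensions `c(nrow, ncol)`.
#' @param p_thresh Cluster-forming p.
#' @param n_perm,seed Permutation settings.
#' @return List of class `cluster_test`: `t` (matrix), `clusters`
#'   (with p_cluster), `dims`.
#' @export
cluster_test_2d <- function(maps, dims, p_thresh = 0.01, n_perm = 2000L,
                            seed = 1L) {
  t <- t_map(maps)
  cl <- threshold_clusters(t, df = nrow(maps) - 1L, p_thresh = p_thresh,
                           dims = dims)
  cl <- permutation_cluster_p(maps, cl, n_perm = n_perm, seed = seed,
                              dims = dims)
  structure(list(t = matrix(t, dims[1], dims[2]), clusters = cl,
                 dims = dims), class = "cluster_test")
}

#' 2D coordinates of the 10-20 montage
#'
#' Schematic top-view positions (unit head radius) for the 19 scalp
#' channels, used to define topographic adjacency.
#'
#' @return data.frame: channel, x, y.
#' @export
chan_coords_1020 <- function() {
  data.frame(
    channel = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3",
                "Cz", "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2"),
    x = c(-0.31, 0.31, -0.81, -0.40, 0, 0.40, 0.81, -1.00, -0.50, 0, 0.50,
          1.00, -0.81, -0.40, 0, 0.40, 0.81, -0.31, 0.31),
    y = c(0.95, 0.95, 0.59, 0.50, 0.50, 0.50, 0.59, 0, 0, 0, 0, 0,
          -0.59, -0.50, -0.50, -0.50, -0.59, -0.95, -0.95))
}

#' Channel adjacency from the 2D layout
#'
#' Channels within `max_dist` of each other (default 0.65 head radii) are
#' adjacent, capped at the `max_deg` nearest before symmetrization, keeping
#' every channel connected to a handful of spatial neighbours (3-8 on the
#' schematic layout).
#'
#' @param coords Layout from [chan_coords_1020()].
#' @param max_dist Distance threshold.
#' @param max_deg Maximum neighbours per channel.
#' @return Named list of character vectors of neighbours.
#' @export
channel_adjacency <- function(coords = chan_coords_1020(), max_dist = 0.65,
                              max_deg = 6L) {
  d <- as.matrix(dist(coords[, c("x", "y")]))
  adj <- lapply(seq_len(nrow(coords)), function(i) {
    nb <- which(d[i, ] > 0 & d[i, ] <= max_dist)
    nb <- nb[order(d[i, nb])]
    coords$channel[head(nb, max_deg)]
  })
  names(adj) <- coords$channel
  # symmetrize after the degree cap
  for (i in seq_along(adj)) for (ch in adj[[i]])
    if (!names(adj)[i] %in% adj[[ch]])
      adj[[ch]] <- c(adj[[ch]], names(adj)[i])
  adj
}

# Adjacency list over channel x bin cells: neighbouring bins within a
# channel, and adjacent channels within a bin. Cell order: channel fastest
# (matrix channel x bin flattened by column).
chanbin_adjacency <- function(channels, n_bins,
                              chan_adj = channel_adjacency()) {
  nch <- length(channels)
  idx <- function(ci, bi) ci + (bi - 1L) * nch
  adj <- vector("list", nch * n_bins)
  for (bi in seq_len(n_bins)) {
    for (ci in seq_len(nch)) {
      nb <- integer(0)
      if (bi > 1L) nb <- c(nb, idx(ci, bi - 1L))
      if (bi < n_bins) nb <- c(nb, idx(ci, bi + 1L))
      for (nc2 in chan_adj[[channels[ci]]]) {
        cj <- match(nc2, channels)
        if (!is.na(cj)) nb <- c(nb, idx(cj, bi))
      }
      adj[[idx(ci, bi)]] <- nb
    }
  }
  adj
}

#' Topographic cluster test on channel x bin band maps
#'
#' Cluster-based permutation inference over the channel x step-cycle-bin
#' graph (neighbouring bins within a channel, spatially adjacent channels
#' within a bin), with the same sign-flip permutation scheme as
#' [cluster_test_2d()]. Supply per-participant difference maps for a
#' condition contrast.
#'
#' @param maps Matrix participants x (channels x bins), cells flattened with
#'   channel varying fastest.
#' @param channels Channel labels.
#' @param n_bins Number of step-cycle bins (default 9).
#' @param chan_adj Channel adjacency list.
#' @param p_thresh,n_perm,seed Test settings.
#' @return List of class `cluster_test`: `t` (channel x bin matrix),
#'   `clusters` with p_cluster.
#' @export
topographic_clusters <- function(maps, channels, n_bins = 9L,
                                 chan_adj = channel_adjacency(),
                                 p_thresh = 0.01, n_perm = 2000L, seed = 1L) {
  if (all(lengths(chan_adj) == 0L))
    warning("adjacency has no edges: every cell clusters alone")
  adj <- chanbin_adjacency(channels, n_bins, chan_adj)
  t <- t_map(maps)
  cl <- threshold_clusters(t, df = nrow(maps) - 1L, p_thresh = p_thresh,
                           adjacency = adj)
  cl <- permutation_cluster_p(maps, cl, n_perm = n_perm, seed = seed,
                              adjacency = adj)
  structure(list(t = matrix(t, length(channels), n_bins,
                            dimnames = list(channels, NULL)),
                 clusters = cl, dims = c(length(channels), n_bins)),
            class = "cluster_test")
}

#' Cluster report
#'
#' Converts a `cluster_test` on a frequency x percentile (or time) map into
#' a human-readable extent report: sign, mass, p, frequency range, axis
#' range and peak location.
#'
#' @param ct A `cluster_test` from [cluster_test_2d()].
#' @param freqs Row coordinate values (Hz).
#' @param xvals Column coordinate values (percentile or ms).
#' @param alpha Report only clusters with p_cluster below this (default 1:
#'   all).
#' @return data.frame: sign, mass, p_cluster, f_lo, f_hi, x_lo, x_hi,
#'   peak_f, peak_x, peak_t.
#' @export
cluster_report <- function(ct, freqs, xvals, alpha = 1) {
  cl <- ct$clusters
  labels <- attr(cl, "labels")
  out <- list()
  for (i in seq_len(nrow(cl))) {
    if (cl$p_cluster[i] > alpha) next
    px <- which(labels == cl$cluster[i], arr.ind = TRUE)
    pk <- arrayInd(cl$peak_idx[i], ct$dims)
    out[[length(out) + 1L]] <- data.frame(
      sign = cl$sign[i], mass = cl$mass[i], p_cluster = cl$p_cluster[i],
      f_lo = min(freqs[px[, 1]]), f_hi = max(freqs[px[, 1]]),
      x_lo = min(xvals[px[, 2]]), x_hi = max(xvals[px[, 2]]),
      peak_f = freqs[pk[1]], peak_x = xvals[pk[2]],
      peak_t = ct$t[pk[1], pk[2]])
  }
  if (!length(out))
    return(data.frame(sign = integer(0), mass = numeric(0),
                      p_cluster = numeric(0), f_lo = numeric(0),
                      f_hi = numeric(0), x_lo = numeric(0), x_hi = numeric(0),
                      peak_f = numeric(0), peak_x = numeric(0),
                      peak_t = numeric(0)))
  do.call(rbind, out)
}
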