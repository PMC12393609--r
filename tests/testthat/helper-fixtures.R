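# Shared fixtures: all built in code, seeded per use.

# AR1 calcium trace from an explicit spike train
ar1_trace <- function(spikes, gamma = 0.9, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.numeric(stats::filter(spikes, gamma, method = "recursive"))
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  y
}

# a bare tail_trace from a numeric vector
tt <- function(x, fs = 100, baseline_removed = TRUE) {
  tail_trace(x, fs, baseline_removed = baseline_removed,
             nan_filled = TRUE)
}

# triangular peak of given height centered in a zero trace
triangle_trace <- function(height, n = 2000, width = 100, center = n / 2,
                           fs = 100, base = 0.5) {
  x <- rep(base * c(1, -1), length.out = n) # tiny alternating floor -> nf
  ramp <- c(seq(0, 1, length.out = width / 2),
            seq(1, 0, length.out = width / 2))
  idx <- (center - width / 2 + 1):(center + width / 2)
  x[idx] <- height * ramp
  tt(x, fs)
}

# naive average-linkage agglomeration on a distance matrix; returns the
# partition (cluster labels) at every cluster count k = n..1
naive_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  labels <- matrix(NA_integer_, n, n)  # labels[, k] = partition at k clusters
  lab <- seq_len(n)
  labels[, n] <- lab
  for (k in seq(n - 1, 1)) {
    m <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < bestd) { bestd <- dij; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
    labels[, k] <- lab
  }
  labels
}

# canonical form of a partition label vector for comparison
canon_partition <- function(lab) {
  match(lab, unique(lab))
}
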