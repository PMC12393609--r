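#' Partition neurons into motor-associated and non-motor clusters
#'
#' Appends the (0-1 normalized) tail trace as the last row of the
#' neuron activity matrix, whose rows are first z-scored over time and
#' then rescaled to \[0, 1\]. One hierarchical tree is built with
#' distance `1 - Spearman rho` and average linkage. Starting from `t0`
#' clusters, the tree is cut with one more cluster per iteration while
#' tracking the cluster containing the tail row; the iteration stops the
#' first time that cluster's size would drop by more than the stability
#' fraction relative to the previous cut, and the previous assignment is
#' returned. Neurons sharing the tail's cluster are motor-associated.
#'
#' @param activity Neurons x frames matrix at the imaging rate (1 Hz).
#' @param tail_1hz Tail-angle vector at the same rate (same length as
#'   `ncol(activity)`); a constant tail trace is an error (undefined
#'   ranks).
#' @param t0 Initial cluster count.
#' @param stability Maximum tolerated fractional drop of the
#'   tail-cluster size per iteration (0.2).
#' @param crop Optional integer range `c(start, stop)` of frames to use
#'   (the manually identified imaging window).
#' @return List of class `cluster_partition`: `motor` (logical per
#'   neuron), `t` (final cluster count), `tail_rho` (per-neuron Spearman
#'   correlation with the tail), `iterations` (t and tail-cluster size
#'   per step), `tree` (the `hclust` object).
#' @export
motor_partition <- function(activity, tail_1hz, t0 = 3,
                            stability = 0.2, crop = NULL) {
  stopifnot(ncol(activity) == length(tail_1hz))
  if (!is.null(crop)) {
    activity <- activity[, crop[1]:crop[2], drop = FALSE]
    tail_1hz <- tail_1hz[crop[1]:crop[2]]
  }
  if (stats::sd(tail_1hz) == 0)
    stop("tail trace is constant: Spearman ranks undefined")
  m <- normalize_rows_01(zscore_rows(activity))
  tail_n <- (tail_1hz - min(tail_1hz)) / diff(range(tail_1hz))
  mat <- rbind(m, tail_n)
  n <- nrow(mat)
  rho <- suppressWarnings(stats::cor(t(mat), method = "spearman"))
  rho[is.na(rho)] <- 0      # constant rows: no rank information
  d <- stats::as.dist(1 - rho)
  tree <- stats::hclust(d, method = "average")
  if (max(tree$height) < 1e-12) {
    # degenerate tree: every row identical in rank -> one cluster
    return(structure(list(motor = rep(TRUE, n - 1), t = 1L,
                          tail_rho = unname(rho[n, -n]),
                          iterations = data.frame(
                            t = 1L, tail_cluster_size = n),
                          tree = tree),
                     class = "cluster_partition"))
  }
  prev <- NULL
  prev_size <- Inf
  iters <- NULL
  for (t in seq(t0, n)) {
    ct <- stats::cutree(tree, k = t)
    size <- sum(ct == ct[n])
    iters <- rbind(iters, c(t = t, tail_cluster_size = size))
    if (!is.null(prev) && size < (1 - stability) * prev_size) {
      ct <- prev
      t <- t - 1
      break
    }
    prev <- ct
    prev_size <- size
    if (size == 1) break
  }
  motor <- ct[-n] == ct[n]
  structure(list(motor = unname(motor), t = t,
                 tail_rho = unname(rho[n, -n]),
                 iterations = as.data.frame(iters), tree = tree),
            class = "cluster_partition")
}

zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  s[s == 0] <- 1
  (m - mu) / s
}

normalize_rows_01 <- function(m) {
  lo <- apply(m, 1, min)
  hi <- apply(m, 1, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  (m - lo) / rng
}

#' Per-region motor/non-motor activity statistics
#'
#' Splits each region's cumulative dF/F between motor-associated and
#' non-motor neurons (the two sums add up to the region total), and
#' reports the motor-neuron count, fraction, and the mean tail
#' correlation of the region's motor neurons.
#'
#' @param partition A `cluster_partition`.
#' @param assigned Neurons x masks logical assignment matrix
#'   (`attr(region_table(...), "assigned")`).
#' @param cum_dff_z Per-neuron z-scored cumulative dF/F.
#' @return Data frame per region: `region`, `motor_cum_dff_z`,
#'   `nonmotor_cum_dff_z`, `n_motor`, `motor_fraction`,
#'   `mean_tail_rho_motor`.
#' @export
per_region_motor_stats <- function(partition, assigned, cum_dff_z) {
  motor <- partition$motor
  rows <- lapply(colnames(assigned), function(r) {
    in_r <- assigned[, r]
    sel_m <- in_r & motor
    sel_n <- in_r & !motor
    data.frame(
      region = r,
      motor_cum_dff_z = sum(cum_dff_z[sel_m]),
      nonmotor_cum_dff_z = sum(cum_dff_z[sel_n]),
      n_motor = sum(sel_m),
      motor_fraction = if (any(in_r)) sum(sel_m) / sum(in_r) else NA_real_,
      mean_tail_rho_motor = if (any(sel_m))
        mean(partition$tail_rho[sel_m]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Region-pair connectivity from high-correlation neuron pairs
#'
#' Spearman correlation is computed between every neuron of region A and
#' every neuron of region B (cross pairs only) on their 1-Hz traces; the
#' connectivity is the percentage of pairs whose correlation exceeds the
#' threshold.
#'
#' @param act_a,act_b Neurons x frames activity matrices of the two
#'   regions (at least one neuron each).
#' @param threshold Correlation threshold (0.8).
#' @return List of class `connectivity_entry`: `n_pairs_total`,
#'   `n_pairs_above`, `connectivity_pct`.
#' @export
connectivity <- function(act_a, act_b, threshold = 0.8) {
  stopifnot(nrow(act_a) >= 1, nrow(act_b) >= 1,
            ncol(act_a) == ncol(act_b))
  rho <- suppressWarnings(
    stats::cor(t(act_a), t(act_b), method = "spearman"))
  rho[is.na(rho)] <- 0
  total <- length(rho)
  above <- sum(rho > threshold)
  structure(list(n_pairs_total = total, n_pairs_above = above,
                 connectivity_pct = 100 * above / total),
            class = "connectivity_entry")
}
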