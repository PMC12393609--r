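#' Build 12-um activity heatmaps for a set of larvae
#'
#' Downsamples each larva's neuron set from the reference grid to
#' coarse isotropic voxels (default 12 x 12 x 12 um): each neuron's
#' metrics accumulate into the voxel containing its centroid
#' (`floor(position_um / 12)`), giving per-voxel active-neuron count,
#' summed z-scored cumulative dF/F and mean firing rate. The heatmap
#' shape is `ceiling(extent_um / 12)` per axis. Rate voxels without
#' neurons are NA (missing, not zero) and are excluded from tests.
#'
#' @param larvae List; each entry needs `centroid_um`, `cum_dff_z`,
#'   `firing_rate_hz`, `active`.
#' @param grid The [reference_grid()] the centroids live on.
#' @param voxel_um Output voxel edge length.
#' @return List of class `voxel_heatmaps`: `count`, `cum_dff`, `rate`
#'   (voxels x larvae matrices), `dim` (heatmap shape), `voxel_um`.
#' @export
build_heatmaps <- function(larvae, grid, voxel_um = 12) {
  dims <- ceiling(grid$extent_um / voxel_um)
  nv <- prod(dims)
  nL <- length(larvae)
  count <- matrix(0, nv, nL)
  cum <- matrix(0, nv, nL)
  rate <- matrix(NA_real_, nv, nL)
  for (i in seq_len(nL)) {
    l <- larvae[[i]]
    act <- l$active
    if (!any(act)) next
    p <- l$centroid_um[act, , drop = FALSE]
    v <- floor(sweep(p, 2, rep(voxel_um, 3), `/`))
    v[v < 0] <- 0
    for (a in 1:3) v[v[, a] >= dims[a], a] <- dims[a] - 1
    lin <- 1 + v[, 1] + v[, 2] * dims[1] + v[, 3] * dims[1] * dims[2]
    count[, i] <- tabulate(lin, nv)
    cum[, i] <- unname(rowsum_vec(l$cum_dff_z[act], lin, nv))
    rsum <- rowsum_vec(l$firing_rate_hz[act], lin, nv)
    nz <- count[, i] > 0
    rate[nz, i] <- rsum[nz] / count[nz, i]
  }
  structure(list(count = count, cum_dff = cum, rate = rate,
                 dim = dims, voxel_um = voxel_um),
            class = "voxel_heatmaps")
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Voxelwise two-group comparison of heatmaps
#'
#' Applies a per-voxel two-sided Wilcoxon rank-sum test across larvae
#' and reports, per metric, the significance mask (p < alpha) and the
#' mean group difference (deficient minus control) masked to the
#' significant voxels. Rate voxels are compared only across larvae with
#' data in that voxel (missing, not zero), and skipped when either group
#' has fewer than two observations.
#'
#' @param hm_control,hm_deficient `voxel_heatmaps` on the same grid.
#' @param alpha Significance level.
#' @return List of class `voxel_comparison` with one entry per metric
#'   (`count`, `cum_dff`, `rate`): `p`, `significant`, `difference`
#'   (masked), plus `dim` and `voxel_um`.
#' @export
voxelwise_test <- function(hm_control, hm_deficient, alpha = 0.05) {
  stopifnot(identical(hm_control$dim, hm_deficient$dim))
  out <- list(dim = hm_control$dim, voxel_um = hm_control$voxel_um,
              alpha = alpha)
  for (metric in c("count", "cum_dff", "rate")) {
    a <- hm_control[[metric]]
    b <- hm_deficient[[metric]]
    nv <- nrow(a)
    p <- rep(NA_real_, nv)
    diff <- rep(NA_real_, nv)
    # test only voxels touched by any larva; elsewhere identical zeros
    touched <- which(rowSums(abs(a) > 0, na.rm = TRUE) +
                       rowSums(abs(b) > 0, na.rm = TRUE) > 0)
    for (v in touched) {
      x <- a[v, ]; y <- b[v, ]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2) next
      p[v] <- rank_sum_test(x, y)
      diff[v] <- mean(y) - mean(x)
    }
    sig <- !is.na(p) & p < alpha
    diff[!sig] <- NA_real_
    out[[metric]] <- list(p = p, significant = sig, difference = diff)
  }
  structure(out, class = "voxel_comparison")
}

#' Map a voxel comparison onto atlas masks and rank by Relevance
#'
#' Downsamples every atlas mask to the heatmap grid (a coarse voxel
#' belongs to the mask if any member fine voxel does) and reports per
#' mask and per metric the percentage of mask voxels significantly
#' increased and decreased, and the summed masked difference in each
#' direction. The Relevance score is the sum of the absolute values of
#' the six directional difference sums (three metrics x two directions);
#' masks are returned sorted by decreasing Relevance.
#'
#' @param cmp A `voxel_comparison`.
#' @param atlas A `toy_atlas` on the grid the heatmaps were built from.
#' @param grid The fine [reference_grid()].
#' @return Data frame per mask with `pct_increased_*`,
#'   `pct_decreased_*`, `sum_increase_*`, `sum_decrease_*` for each
#'   metric and the total `relevance`.
#' @export
map_to_masks <- function(cmp, atlas, grid) {
  dims <- cmp$dim
  vox <- cmp$voxel_um
  coarse_masks <- lapply(atlas$masks, function(m) {
    ijk <- arrayInd(m, atlas$grid$shape)
    um <- sweep(ijk - 0.5, 2, atlas$grid$voxel_size_um, `*`)
    v <- floor(um / vox)
    for (a in 1:3) v[v[, a] >= dims[a], a] <- dims[a] - 1
    unique(1 + v[, 1] + v[, 2] * dims[1] + v[, 3] * dims[1] * dims[2])
  })
  rows <- lapply(names(coarse_masks), function(nm) {
    idx <- coarse_masks[[nm]]
    row <- list(region = nm, n_voxels_12um = length(idx))
    rel <- 0
    for (metric in c("count", "cum_dff", "rate")) {
      d <- cmp[[metric]]$difference[idx]
      up <- !is.na(d) & d > 0
      dn <- !is.na(d) & d < 0
      row[[paste0("pct_increased_", metric)]] <- 100 * sum(up) / length(idx)
      row[[paste0("pct_decreased_", metric)]] <- 100 * sum(dn) / length(idx)
      si <- sum(d[up]); sd <- sum(d[dn])
      row[[paste0("sum_increase_", metric)]] <- si
      row[[paste0("sum_decrease_", metric)]] <- sd
      rel <- rel + abs(si) + abs(sd)
    }
    row$relevance <- rel
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  out[order(-out$relevance), ]
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact distribution when both samples have at most 10 observations and
#' no ties are present; normal approximation with tie correction
#' otherwise.
#'
#' @param x,y Numeric samples.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Two-sided permutation test on the difference of means
#'
#' Enumerates all group-label assignments exactly when their number is
#' at most `exact_max`, otherwise Monte-Carlo samples `n_perm`
#' permutations (seeded). The p-value is the fraction of permuted
#' absolute mean differences at least as large as the observed one
#' (with the identity permutation included for sampled p, so
#' p >= 1 / (n_perm + 1)).
#'
#' @param x,y Numeric samples.
#' @param n_perm Monte-Carlo permutation count.
#' @param seed Seed for the sampled branch.
#' @param exact_max Enumeration limit on `choose(nx + ny, nx)`.
#' @return Two-sided p-value.
#' @export
permutation_test <- function(x, y, n_perm = 10000, seed = NULL,
                             exact_max = 20000) {
  pool <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  tol <- 1e-12 * (1 + obs)
  if (choose(length(pool), nx) <= exact_max) {
    splits <- utils::combn(length(pool), nx)
    stat <- apply(splits, 2, function(i)
      abs(mean(pool[i]) - mean(pool[-i])))
    mean(stat >= obs - tol)
  } else {
    if (!is.null(seed)) set.seed(seed)
    stat <- replicate(n_perm, {
      i <- sample.int(length(pool), nx)
      abs(mean(pool[i]) - mean(pool[-i]))
    })
    (1 + sum(stat >= obs - tol)) / (n_perm + 1)
  }
}

#' Region-level two-group test
#'
#' Compares a per-larva region statistic between groups for every
#' region: two-sided rank-sum p-value, optionally also the permutation
#' p-value with the reported p being the larger of the two, and the
#' effect size as the percent change of the deficient group mean
#' relative to the control mean.
#'
#' @param tables_control,tables_deficient Lists of per-larva region
#'   tables from [region_table()] (aligned region order).
#' @param metric Column to compare: `"n_active"`, `"sum_cum_dff_z"` or
#'   `"mean_rate_hz"`.
#' @param alpha Significance level.
#' @param permutation Also run the permutation test and report the
#'   larger p-value.
#' @param n_perm,seed Passed to [permutation_test()].
#' @return Data frame per region: `region`, `division`, `mean_control`,
#'   `mean_deficient`, `pct_change`, `p`, `significant`, `direction`.
#' @export
region_test <- function(tables_control, tables_deficient,
                        metric = "n_active", alpha = 0.05,
                        permutation = FALSE, n_perm = 10000,
                        seed = NULL) {
  regions <- tables_control[[1]]$region
  get_vals <- function(tabs, r)
    vapply(tabs, function(t) t[[metric]][t$region == r], numeric(1))
  rows <- lapply(regions, function(r) {
    x <- get_vals(tables_control, r)
    y <- get_vals(tables_deficient, r)
    ok <- sum(!is.na(x)) >= 2 && sum(!is.na(y)) >= 2
    p <- NA_real_
    if (ok) {
      p <- rank_sum_test(x[!is.na(x)], y[!is.na(y)])
      if (permutation)
        p <- max(p, permutation_test(x[!is.na(x)], y[!is.na(y)],
                                     n_perm = n_perm, seed = seed))
    }
    mc <- mean(x, na.rm = TRUE); md <- mean(y, na.rm = TRUE)
    data.frame(
      region = r,
      division = tables_control[[1]]$division[
        tables_control[[1]]$region == r],
      mean_control = mc, mean_deficient = md,
      pct_change = if (!is.na(mc) && mc != 0) 100 * (md - mc) / mc
        else NA_real_,
      p = p,
      significant = !is.na(p) & p < alpha,
      direction = if (is.na(mc) || is.na(md) || md == mc) "none"
        else if (md > mc) "increase" else "decrease")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
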