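fake_larva <- function(centroids, cum, rate, active = NULL) {
  if (is.null(active)) active <- rep(TRUE, nrow(centroids))
  list(centroid_um = centroids, cum_dff_z = cum, firing_rate_hz = rate,
       active = active)
}

test_that("heatmap accumulation and conservation semantics hold", {
  grid <- reference_grid(c(60, 60, 30))
  # one neuron -> one voxel with count 1
  l1 <- fake_larva(matrix(c(20, 20, 20), 1), 1.5, 0.05)
  hm <- build_heatmaps(list(l1), grid)
  expect_equal(sum(hm$count[, 1]), 1)
  expect_equal(sum(hm$count[, 1] > 0), 1)
  # two neurons in the same 12-um voxel: count 2, dF/F summed, rate
  # averaged
  l2 <- fake_larva(rbind(c(25, 25, 25), c(30, 30, 28)),
                   c(1, 2), c(0.02, 0.06))
  hm2 <- build_heatmaps(list(l2), grid)
  v <- which(hm2$count[, 1] == 2)
  expect_equal(length(v), 1)
  expect_equal(hm2$cum_dff[v, 1], 3)
  expect_equal(hm2$rate[v, 1], 0.04)
  # total count equals the active-neuron count
  set.seed(41)
  cen <- cbind(runif(50, 0, 60), runif(50, 0, 60), runif(50, 0, 60))
  act <- runif(50) < 0.7
  l3 <- fake_larva(cen, rnorm(50), runif(50), act)
  hm3 <- build_heatmaps(list(l3), grid)
  expect_equal(sum(hm3$count[, 1]), sum(act))
  # empty-voxel rates are missing, not zero
  expect_true(all(is.na(hm3$rate[hm3$count[, 1] == 0, 1])))
})

test_that("identical groups yield no significant voxels", {
  grid <- reference_grid(c(60, 60, 30))
  set.seed(42)
  mk <- function() fake_larva(cbind(runif(20, 0, 60), runif(20, 0, 60),
                                    runif(20, 0, 60)),
                              rnorm(20), runif(20))
  larvae <- replicate(6, mk(), simplify = FALSE)
  hm <- build_heatmaps(larvae, grid)
  cmp <- voxelwise_test(hm, hm)
  for (m in c("count", "cum_dff", "rate"))
    expect_equal(sum(cmp[[m]]$significant), 0)
})

test_that("rank-sum p-values match exact enumeration for small samples", {
  # oracle: full enumeration of the rank-sum distribution
  enum_p <- function(x, y) {
    n <- length(x); m <- length(y)
    r <- rank(c(x, y))
    w <- sum(r[seq_len(n)])
    splits <- utils::combn(n + m, n)
    ws <- apply(splits, 2, function(i) sum(r[i]))
    mu <- n * (n + m + 1) / 2
    mean(abs(ws - mu) >= abs(w - mu) - 1e-12)
  }
  set.seed(43)
  for (rep in 1:8) {
    x <- rnorm(sample(4:7, 1)); y <- rnorm(sample(4:7, 1), 0.8)
    expect_equal(rank_sum_test(x, y), enum_p(x, y), tolerance = 1e-10)
  }
})

test_that("permutation test matches brute force on the 3-vs-3 case", {
  x <- c(1.2, 3.4, 0.5); y <- c(4.1, 5.0, 6.3)
  # oracle: all 20 label splits of the pooled values
  pool <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  splits <- utils::combn(6, 3)
  stats <- apply(splits, 2, function(i)
    abs(mean(pool[i]) - mean(pool[-i])))
  oracle <- mean(stats >= obs - 1e-12)
  expect_equal(permutation_test(x, y), oracle)
  # constant identical samples -> p = 1
  expect_equal(permutation_test(rep(2, 4), rep(2, 4)), 1)
  # sampled branch is seed-stable
  set.seed(44)
  xl <- rnorm(12); yl <- rnorm(12, 1)
  p1 <- permutation_test(xl, yl, n_perm = 500, seed = 7, exact_max = 10)
  p2 <- permutation_test(xl, yl, n_perm = 500, seed = 7, exact_max = 10)
  expect_equal(p1, p2)
  expect_gte(p1, 1 / 501)
})

test_that("relevance is the absolute sum of directional components", {
  # direct check of the mask mapping on a constructed comparison
  grid <- reference_grid(c(24, 24, 12))
  dims <- ceiling(grid$extent_um / 12)
  nv <- prod(dims)
  cmp <- structure(list(dim = dims, voxel_um = 12, alpha = 0.05),
                   class = "voxel_comparison")
  for (m in c("count", "cum_dff", "rate")) {
    d <- rep(NA_real_, nv)
    cmp[[m]] <- list(p = rep(NA, nv), significant = rep(FALSE, nv),
                     difference = d)
  }
  # mask covering coarse voxels 1:4 with differences 2, -1, 3, -4 on
  # one metric and 0 elsewhere -> relevance = |5| + |-5| = 10
  cmp$count$difference[1:4] <- c(2, -1, 3, -4)
  atlas <- list(grid = grid,
                masks = list(m = 1:(2 * 24 * 12)),  # fine voxels, x 1:2
                manifest = data.frame(name = "m", parent = NA,
                                      class = "base", division = "x",
                                      n_voxels = NA))
  # fine voxels with x 1:24, y 1:24, z 1:12 all map into coarse x 1:2
  atlas$masks$m <- seq_len(prod(grid$shape))
  rel <- map_to_masks(cmp, atlas, grid)
  expect_equal(rel$sum_increase_count, 5)
  expect_equal(rel$sum_decrease_count, -5)
  expect_equal(rel$relevance, 10)
  # all-zero differences -> relevance 0
  cmp$count$difference[] <- NA_real_
  expect_equal(map_to_masks(cmp, atlas, grid)$relevance, 0)
})

test_that("region tests report percent change and exact identity cases", {
  mk_tab <- function(vals) data.frame(region = c("a", "b"),
                                      division = "midbrain",
                                      n_active = vals,
                                      sum_cum_dff_z = vals,
                                      mean_rate_hz = vals / 100,
                                      empty = FALSE)
  ctrl <- lapply(c(100, 102, 98, 101), function(v) mk_tab(c(v, 50)))
  defc <- lapply(c(131, 130, 132, 131), function(v) mk_tab(c(v, 50)))
  rt <- region_test(ctrl, defc, metric = "n_active")
  expect_equal(rt$pct_change[rt$region == "a"],
               100 * (131 - 100.25) / 100.25)
  expect_true(rt$significant[rt$region == "a"])
  expect_equal(rt$direction[rt$region == "a"], "increase")
  # identical groups: p = 1 under ties, 0% change
  rt2 <- region_test(ctrl, ctrl, metric = "n_active")
  expect_equal(rt2$pct_change, c(0, 0))
  expect_false(any(rt2$significant))
  # plain arithmetic: control mean 100, deficient 131 -> +31%
  c3 <- lapply(rep(100, 4), function(v) mk_tab(c(v, 1)))
  d3 <- lapply(rep(131, 4), function(v) mk_tab(c(v, 1)))
  expect_equal(region_test(c3, d3)$pct_change[1], 31)
})

test_that("a planted regional effect is detected and ranked first", {
  atlas <- generate_toy_atlas(shape_voxels = c(60, 120, 30),
                              n_regions = 4, seed = 45)
  spec <- cohort_spec(n_control = 10, n_deficient = 10,
                      neurons_per_larva = 1000,
                      effect_active_neurons = 0.5,
                      effect_firing_rate = -0.3,
                      affected_region_labels = "region02",
                      duration_s = 300, seed = 46)
  coh <- generate_calcium_cohort(spec, atlas = atlas, traces = FALSE)
  set.seed(47)
  larvae <- lapply(coh$larvae, function(lv)
    fake_larva(lv$centroid_um,
               cum = rnorm(length(lv$active), 1, 0.1),
               rate = lv$true_spike_count / 300,
               active = lv$active))
  grp <- vapply(coh$larvae, function(l) l$group, character(1))
  hm_c <- build_heatmaps(larvae[grp == "control"], atlas$grid)
  hm_d <- build_heatmaps(larvae[grp == "deficient"], atlas$grid)
  cmp <- voxelwise_test(hm_c, hm_d)
  rel <- map_to_masks(cmp, atlas, atlas$grid)
  base_rel <- rel[rel$region %in% paste0("region0", 1:4), ]
  expect_equal(base_rel$region[1], "region02")  # sorted by relevance
  # most significant count voxels concentrate in the affected region
  expect_gt(base_rel$pct_increased_count[1],
            3 * max(base_rel$pct_increased_count[-1]))
})
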