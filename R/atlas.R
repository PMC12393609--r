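#' Reference voxel grid
#'
#' The registration grid on which atlas masks and neuron centroids live.
#' The full-scale grid is 500 x 1000 x 200 voxels of 1 x 1 x 2 um
#' (500 um x 1000 um x 400 um); the toy atlas uses a smaller grid with
#' the same voxel semantics.
#'
#' @param shape_voxels Integer (x, y, z) grid shape.
#' @param voxel_size_um Physical voxel size.
#' @return Object of class `reference_grid` with `shape`,
#'   `voxel_size_um` and `extent_um`.
#' @export
reference_grid <- function(shape_voxels = c(500, 1000, 200),
                           voxel_size_um = c(1, 1, 2)) {
  shape <- as.integer(shape_voxels)
  stopifnot(length(shape) == 3, all(shape > 0), all(voxel_size_um > 0))
  structure(list(shape = shape, voxel_size_um = voxel_size_um,
                 extent_um = shape * voxel_size_um),
            class = "reference_grid")
}

#' Voxel cube representing one neuron
#'
#' An axis-aligned 5 x 5 x 6 um box centered on the neuron centroid
#' (after the 5-um z-offset that compensates the steady objective motion
#' during volumetric acquisition), rasterized on the 1 x 1 x 2 um grid:
#' the centroid voxel plus or minus 2 voxels in x and y and plus or minus
#' 1 in z, i.e. 5 x 5 x 3 = 75 voxels for an interior centroid. The cube
#' is clipped at the volume border; a centroid outside the grid yields an
#' empty set with a warning.
#'
#' @param centroid_um Length-3 (x, y, z) position in micrometres,
#'   reference space.
#' @param grid A [reference_grid()].
#' @param z_offset_um Offset added to z before voxelization (half the
#'   10-um volumetric z-step).
#' @return Integer matrix of voxel coordinates (1-based columns x, y, z),
#'   possibly with zero rows.
#' @export
neuron_cube <- function(centroid_um, grid, z_offset_um = 5) {
  p <- as.numeric(centroid_um)
  p[3] <- p[3] + z_offset_um
  vs <- grid$voxel_size_um
  v <- floor(p / vs) + 1L     # 1-based voxel containing the centroid
  if (any(v < 1L) || any(v > grid$shape)) {
    warning("centroid outside the reference grid; empty cube")
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  half <- c(2L, 2L, 1L)
  rx <- max(1L, v[1] - half[1]):min(grid$shape[1], v[1] + half[1])
  ry <- max(1L, v[2] - half[2]):min(grid$shape[2], v[2] + half[2])
  rz <- max(1L, v[3] - half[3]):min(grid$shape[3], v[3] + half[3])
  out <- as.matrix(expand.grid(x = rx, y = ry, z = rz,
                               KEEP.OUT.ATTRS = FALSE))
  storage.mode(out) <- "integer"
  out
}

# linear (column-major) voxel indices of a cube on a grid
cube_linear_index <- function(cube, grid) {
  if (!nrow(cube)) return(integer(0))
  cube[, 1] + (cube[, 2] - 1L) * grid$shape[1] +
    (cube[, 3] - 1L) * grid$shape[1] * grid$shape[2]
}

#' Assign a neuron cube to atlas regions by overlap
#'
#' A neuron belongs to every mask its cube overlaps in at least
#' `min_overlap` voxels (10); overlapping masks make the relation
#' many-to-many by design.
#'
#' @param cube Voxel matrix from [neuron_cube()].
#' @param atlas A `toy_atlas` (or any list with `grid` and `masks` of
#'   linear voxel indices).
#' @param min_overlap Minimum overlapping voxel count.
#' @return Character vector of assigned mask names.
#' @export
assign_regions <- function(cube, atlas, min_overlap = 10) {
  lin <- cube_linear_index(cube, atlas$grid)
  if (!length(lin)) return(character(0))
  hit <- vapply(atlas$masks, function(m) sum(lin %in% m), numeric(1))
  names(hit)[hit >= min_overlap]
}

# overlap counts of many neurons against all masks at once; returns a
# neurons x masks integer matrix (used by region_table)
overlap_matrix <- function(centroids_um, atlas, min_overlap = 10,
                           z_offset_um = 5) {
  n <- nrow(centroids_um)
  masks <- atlas$masks
  memb <- logical(prod(atlas$grid$shape))
  out <- matrix(0L, n, length(masks),
                dimnames = list(NULL, names(masks)))
  cubes <- lapply(seq_len(n), function(i) {
    cube_linear_index(suppressWarnings(
      neuron_cube(centroids_um[i, ], atlas$grid, z_offset_um)),
      atlas$grid)
  })
  for (m in seq_along(masks)) {
    memb[masks[[m]]] <- TRUE
    out[, m] <- vapply(cubes, function(lin) sum(memb[lin]), integer(1))
    memb[masks[[m]]] <- FALSE
  }
  out
}

#' Per-region activity table for one larva
#'
#' For every atlas mask: the number of active assigned neurons, the sum
#' of their z-scored cumulative dF/F, and their mean firing rate (NA and
#' flagged when the region holds no active neuron). A neuron may
#' contribute to several overlapping masks. Region rows carry the
#' forebrain/midbrain/hindbrain division of their mask.
#'
#' @param centroids_um Neurons x 3 centroid matrix.
#' @param cum_dff_z,firing_rate_hz Per-neuron statistics.
#' @param active Logical per-neuron activity flag.
#' @param atlas A `toy_atlas`.
#' @param min_overlap Cube-overlap threshold for assignment.
#' @return Data frame, one row per mask: `region`, `division`,
#'   `n_active`, `sum_cum_dff_z`, `mean_rate_hz`, `empty`.
#' @export
region_table <- function(centroids_um, cum_dff_z, firing_rate_hz,
                         active, atlas, min_overlap = 10) {
  ov <- overlap_matrix(centroids_um, atlas, min_overlap)
  assigned <- ov >= min_overlap
  man <- atlas$manifest
  rows <- lapply(seq_along(atlas$masks), function(m) {
    sel <- assigned[, m] & active
    data.frame(
      region = names(atlas$masks)[m],
      division = man$division[match(names(atlas$masks)[m], man$name)],
      n_active = sum(sel),
      sum_cum_dff_z = sum(cum_dff_z[sel]),
      mean_rate_hz = if (any(sel)) mean(firing_rate_hz[sel]) else NA_real_,
      empty = !any(sel))
  })
  out <- do.call(rbind, rows)
  attr(out, "assigned") <- assigned
  out
}

#' Full-scale atlas mask inventory
#'
#' The region/marker sources the full-scale pipeline configuration is
#' built around: anatomical masks from the two larval zebrafish
#' reference atlases plus in-situ/transgenic expression markers, each
#' further subdivided by neurotransmitter class downstream.
#'
#' @return Data frame with one row per mask source (`source`,
#'   `n_masks`).
#' @export
atlas_sources <- function() {
  data.frame(
    source = c("zbrain_anatomical", "mapzebrain_anatomical",
               "expression_markers"),
    n_masks = c(294L, 114L, 296L))
}

#' Quantify marker-channel signal loss after chemogenetic ablation
#'
#' Counts suprathreshold voxels of 0-1 normalized marker volumes inside
#' each composite mask for a control and a treated group and reports the
#' percent loss `100 * (a - b) / a`, where `a` and `b` are the group
#' totals. The counting threshold starts at `t0` and is adjusted over a
#' small grid: for each candidate threshold the per-larva counts are
#' screened for outliers (more than 3 scaled median absolute deviations
#' from the group median) and the threshold with the fewest outliers
#' wins, ties resolved toward `t0`.
#'
#' @param control_vols,treated_vols Lists of 0-1 normalized numeric
#'   arrays on the mask grid (one per larva; any chromatic z-offset is
#'   applied upstream).
#' @param masks Named list of linear voxel index vectors (composite
#'   masks).
#' @param t0 Initial threshold.
#' @param step,range Threshold grid step and bounds.
#' @param mad_k Outlier rule multiplier.
#' @return Data frame per mask: `mask`, `a`, `b`, `percent_loss`,
#'   `threshold`.
#' @export
quantify_ablation <- function(control_vols, treated_vols, masks,
                              t0 = 0.2, step = 0.05,
                              range = c(0.1, 0.5), mad_k = 3) {
  stopifnot(t0 > 0, t0 < 1)
  thr_grid <- seq(range[1], range[2], by = step)
  counts_at <- function(vols, mask, thr)
    vapply(vols, function(v) sum(v[mask] > thr), numeric(1))
  n_outliers <- function(x) {
    m <- stats::median(x); s <- stats::mad(x)
    if (s == 0) 0L else sum(abs(x - m) > mad_k * s)
  }
  rows <- lapply(names(masks), function(nm) {
    mask <- masks[[nm]]
    score <- vapply(thr_grid, function(th)
      n_outliers(counts_at(control_vols, mask, th)) +
        n_outliers(counts_at(treated_vols, mask, th)), numeric(1))
    best <- thr_grid[score == min(score)]
    thr <- best[which.min(abs(best - t0))]
    a <- sum(counts_at(control_vols, mask, thr))
    b <- sum(counts_at(treated_vols, mask, thr))
    data.frame(mask = nm, a = a, b = b,
               percent_loss = if (a > 0) 100 * (a - b) / a else NA_real_,
               threshold = thr)
  })
  do.call(rbind, rows)
}
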