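#' Cohort specification for synthetic two-group calcium imaging data
#'
#' Describes a two-group experiment (vehicle-treated controls vs
#' catecholamine-deficient larvae) with planted effects on the number of
#' active neurons and on per-neuron event rates, restricted to a set of
#' affected atlas regions.
#'
#' @param n_control,n_deficient Number of larvae per group.
#' @param neurons_per_larva Candidate neurons placed per larva.
#' @param effect_active_neurons Relative change of the active-neuron
#'   fraction in the deficient group inside affected regions (e.g. `0.30`
#'   for 30% more active neurons).
#' @param effect_firing_rate Relative change of the per-neuron spike rate
#'   in the deficient group inside affected regions (e.g. `-0.25` for a
#'   25% lower rate).
#' @param affected_region_labels Character vector of base-region names of
#'   the toy atlas that carry the planted effects.
#' @param duration_s Recording duration in seconds (traces are at 1 Hz).
#' @param frame_rate_hz Imaging rate in Hz.
#' @param active_fraction Baseline probability that a neuron is active
#'   (has a nonzero spike rate) in the control condition.
#' @param rate_hz Baseline per-neuron spike rate of active neurons.
#' @param seed Integer seed; fully determines every generated number.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 10, n_deficient = 10,
                        neurons_per_larva = 300,
                        effect_active_neurons = 0.30,
                        effect_firing_rate = -0.25,
                        affected_region_labels = NULL,
                        duration_s = 1445, frame_rate_hz = 1,
                        active_fraction = 0.6, rate_hz = 0.05,
                        seed = 1L) {
  stopifnot(n_control >= 1, n_deficient >= 1, neurons_per_larva >= 1,
            duration_s > 0, frame_rate_hz > 0,
            active_fraction > 0, active_fraction <= 1, rate_hz >= 0)
  structure(list(
    n_control = as.integer(n_control),
    n_deficient = as.integer(n_deficient),
    neurons_per_larva = as.integer(neurons_per_larva),
    effect_active_neurons = effect_active_neurons,
    effect_firing_rate = effect_firing_rate,
    affected_region_labels = affected_region_labels,
    duration_s = duration_s,
    frame_rate_hz = frame_rate_hz,
    active_fraction = active_fraction,
    rate_hz = rate_hz,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic two-group calcium imaging cohort
#'
#' Inverts the AR1 inference model used downstream: for every active
#' neuron a Poisson spike train `s_t` is drawn, calcium follows
#' `c_t = gamma * c_(t-1) + s_t`, and fluorescence is
#' `F_t = alpha * c_t + beta_t + eps_t` with a slow sinusoidal drift
#' `beta_t` (period >= 5 min, so the 2-min moving-baseline subtraction has
#' something to remove) and Gaussian noise `eps_t`. Deficient larvae have
#' their active-neuron fraction and per-neuron spike rate scaled by the
#' planted effects inside the affected regions only.
#'
#' @param spec A [cohort_spec()].
#' @param atlas A toy atlas from [generate_toy_atlas()]; generated with
#'   defaults (seeded from `spec$seed`) when `NULL`.
#' @param gamma AR1 calcium decay coefficient, must lie in (0, 1).
#' @param alpha Fluorescence gain per unit calcium.
#' @param noise_sd Gaussian noise s.d. of the fluorescence trace.
#' @param drift_amp,drift_period_s Amplitude and period of the sinusoidal
#'   baseline drift.
#' @param traces If `FALSE`, spike trains and fluorescence traces are not
#'   materialized; only per-neuron spike counts, activity flags and
#'   region assignments are generated (identical distribution, much
#'   cheaper; used for large statistical-power runs).
#' @return A list with `larvae` (one entry per larva holding centroids,
#'   region labels, group, and — when `traces = TRUE` — spike/fluorescence
#'   matrices with one column per neuron) and `ground_truth` (planted
#'   per-neuron truth and effect sizes).
#' @export
generate_calcium_cohort <- function(spec, atlas = NULL, gamma = 0.9,
                                    alpha = 1, noise_sd = 0.2,
                                    drift_amp = 0.3, drift_period_s = 600,
                                    traces = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (gamma <= 0 || gamma >= 1)
    stop("gamma must lie strictly inside (0, 1)")
  if (drift_period_s < 300)
    stop("drift_period_s must be >= 300 s (slow drift)")
  set.seed(spec$seed)
  if (is.null(atlas))
    atlas <- generate_toy_atlas(seed = spec$seed + 1L)
  regions <- atlas$manifest$name[atlas$manifest$class == "base"]
  affected <- spec$affected_region_labels
  if (is.null(affected)) affected <- character(0)
  unknown <- setdiff(affected, regions)
  if (length(unknown))
    stop("affected_region_labels not in atlas: ",
         paste(unknown, collapse = ", "))

  n_frames <- round(spec$duration_s * spec$frame_rate_hz)
  groups <- c(rep("control", spec$n_control),
              rep("deficient", spec$n_deficient))
  larvae <- vector("list", length(groups))
  gt_rows <- vector("list", length(groups))

  for (i in seq_along(groups)) {
    grp <- groups[i]
    n <- spec$neurons_per_larva
    region <- sample(regions, n, replace = TRUE)
    centroid <- atlas_random_centroids(atlas, region)
    in_aff <- region %in% affected
    p_active <- rep(spec$active_fraction, n)
    rate <- rep(spec$rate_hz, n)
    if (grp == "deficient") {
      p_active[in_aff] <- pmin(0.95, p_active[in_aff] *
                                 (1 + spec$effect_active_neurons))
      rate[in_aff] <- pmax(0, rate[in_aff] * (1 + spec$effect_firing_rate))
    }
    active <- stats::rbinom(n, 1L, p_active) == 1L
    lam <- ifelse(active, rate / spec$frame_rate_hz, 0)
    if (traces) {
      spikes <- matrix(0, n_frames, n)
      spikes[, active] <- stats::rpois(n_frames * sum(active),
                                       rep(lam[active],
                                           each = n_frames))
      calcium <- apply(spikes, 2, function(s)
        stats::filter(s, gamma, method = "recursive"))
      tt <- seq_len(n_frames) / spec$frame_rate_hz
      phase <- stats::runif(n, 0, 2 * pi)
      drift <- drift_amp * sin(outer(2 * pi * tt / drift_period_s,
                                     phase, `+`))
      raw <- alpha * calcium + drift +
        matrix(stats::rnorm(n_frames * n, 0, noise_sd), n_frames, n)
      spike_count <- colSums(spikes)
    } else {
      spikes <- NULL
      raw <- NULL
      spike_count <- stats::rpois(n, lam * n_frames)
    }
    larvae[[i]] <- list(
      id = sprintf("larva%02d", i), group = grp,
      centroid_um = centroid, region = region,
      active = active, true_rate_hz = rate * as.numeric(active),
      true_spike_count = spike_count,
      spikes = spikes, raw = raw,
      frame_rate_hz = spec$frame_rate_hz, duration_s = spec$duration_s)
    gt_rows[[i]] <- data.frame(
      larva = larvae[[i]]$id, group = grp,
      neuron = seq_len(n), region = region, active = active,
      true_rate_hz = rate * as.numeric(active),
      true_spike_count = spike_count)
  }
  list(larvae = larvae,
       ground_truth = list(
         neurons = do.call(rbind, gt_rows),
         affected_regions = affected,
         effect_active_neurons = spec$effect_active_neurons,
         effect_firing_rate = spec$effect_firing_rate,
         gamma = gamma, spec = spec),
       atlas = atlas)
}

# Draw one random in-region voxel per requested region label and convert
# to micrometre coordinates at the voxel centre.
atlas_random_centroids <- function(atlas, region) {
  vs <- atlas$grid$voxel_size_um
  out <- matrix(NA_real_, length(region), 3,
                dimnames = list(NULL, c("x", "y", "z")))
  for (r in unique(region)) {
    idx <- which(region == r)
    vox <- atlas$masks[[r]]
    pick <- vox[sample.int(length(vox), length(idx), replace = TRUE)]
    ijk <- arrayInd(pick, atlas$grid$shape)
    out[idx, ] <- sweep(ijk - 0.5, 2, vs, `*`)
  }
  out
}

#' Generate a synthetic tail-angle trace with planted events
#'
#' Builds a baseline-corrupted tail-angle time series from an explicit
#' event plan. Event amplitudes are given in degrees; the helper
#' [tail_event_plan()] expresses them in units of the nominal noise floor
#' (the noise s.d.) so every classifier threshold (3x, 10x, 20x) can be
#' straddled deliberately. Noise is drawn from a normal distribution
#' truncated at 2.5 s.d. — tail-angle jitter of an immobile tail is
#' bounded, and unbounded Gaussian tails would plant spurious
#' threshold crossings at high frame rates that no real trace shows.
#'
#' Event waveforms: `swim` is an asymmetric burst oscillation (opposite
#' side at 78% amplitude), `right_flip`/`left_flip` are one-sided humps,
#' and `struggle` is a large bidirectional oscillation with both extremes
#' at full amplitude.
#'
#' @param event_plan Data frame with columns `type` (one of swim,
#'   right_flip, left_flip, struggle), `onset_s`, `duration_s`,
#'   `amplitude_deg`.
#' @param noise_sd Noise s.d. in degrees (the nominal noise floor).
#' @param drift_amp Amplitude of a slow sinusoidal baseline drift
#'   (degrees); exercises the 1-min bidirectional baseline removal.
#' @param drift_period_s Drift period in seconds.
#' @param frame_rate Sampling rate in Hz.
#' @param duration_s Total trace duration.
#' @param seed Integer seed.
#' @param allow_overlap Permit events closer than 2 s (for testing the
#'   downstream merge rule); otherwise such plans are rejected.
#' @return List with `trace` (a `tail_trace`), `labels` (per-frame true
#'   event type, "none" outside events) and `events` (the realized plan).
#' @export
generate_tail_trace <- function(event_plan, noise_sd = 1.5,
                                drift_amp = 2, drift_period_s = 300,
                                frame_rate = 200, duration_s = 60,
                                seed = 1L, allow_overlap = FALSE) {
  stopifnot(noise_sd >= 0, frame_rate > 0, duration_s > 0)
  plan <- as.data.frame(event_plan)
  if (nrow(plan)) {
    stopifnot(all(c("type", "onset_s", "duration_s", "amplitude_deg")
                  %in% names(plan)))
    bad <- setdiff(plan$type,
                   c("swim", "right_flip", "left_flip", "struggle"))
    if (length(bad)) stop("unknown event type: ", paste(bad, collapse = ", "))
    plan <- plan[order(plan$onset_s), , drop = FALSE]
    if (!allow_overlap && nrow(plan) > 1) {
      gaps <- plan$onset_s[-1] - (plan$onset_s + plan$duration_s)[-nrow(plan)]
      if (any(gaps < 2))
        stop("events closer than the 2-s merge spacing; ",
             "set allow_overlap = TRUE to test the merge rule")
    }
    if (any(plan$onset_s < 0 | plan$onset_s + plan$duration_s > duration_s))
      stop("event plan exceeds trace duration")
  }
  set.seed(seed)
  n <- round(duration_s * frame_rate)
  tt <- seq_len(n) / frame_rate
  # truncated normal via inverse-cdf on a restricted uniform range
  trunc <- 2.5
  u <- stats::runif(n, stats::pnorm(-trunc), stats::pnorm(trunc))
  x <- noise_sd * stats::qnorm(u)
  drift <- drift_amp * sin(2 * pi * tt / drift_period_s +
                             stats::runif(1, 0, 2 * pi))
  labels <- rep("none", n)
  for (k in seq_len(nrow(plan))) {
    i0 <- max(1L, round(plan$onset_s[k] * frame_rate) + 1L)
    i1 <- min(n, round((plan$onset_s[k] + plan$duration_s[k]) * frame_rate))
    if (i1 < i0) next
    x[i0:i1] <- x[i0:i1] +
      tail_event_waveform(plan$type[k], i1 - i0 + 1L,
                          plan$amplitude_deg[k], frame_rate)
    labels[i0:i1] <- plan$type[k]
  }
  trace <- tail_trace(x + drift, frame_rate,
                      baseline_removed = FALSE, nan_filled = TRUE)
  list(trace = trace, labels = labels, events = plan)
}

# One event waveform sampled at the trace rate. Amplitude is the peak in
# degrees; envelope is sin^2 so the event ramps smoothly from zero.
tail_event_waveform <- function(type, n, amplitude, frame_rate) {
  s <- seq(0, 1, length.out = n)
  env <- sin(pi * s)^2
  beat_hz <- 18
  osc <- sin(2 * pi * beat_hz * s * (n / frame_rate))
  w <- switch(type,
    swim = {
      v <- osc
      v[v < 0] <- 0.78 * v[v < 0]       # weaker off side: not a flip
      amplitude * env * v
    },
    right_flip = amplitude * env * abs(osc),
    left_flip = -amplitude * env * abs(osc),
    struggle = amplitude * env * osc,
    stop("unknown event type: ", type))
  # guarantee the planted peak reaches the requested amplitude
  m <- max(abs(w))
  if (m > 0) w <- w * (amplitude / m)
  w
}

#' Convenience event plan in noise-floor units
#'
#' Builds an event plan whose amplitudes are multiples of the nominal
#' noise floor (`noise_sd`), with defaults that straddle the classifier
#' thresholds: swims peak at 7x (off side 5.5x), flips at 9x one-sided,
#' struggles at 18x on both sides. The default spacing keeps the event
#' duty cycle under 5% so the realized noise floor (which includes event
#' samples) stays close to the nominal one and the planted multiples
#' remain on the intended side of each threshold.
#'
#' @param types Character vector of event types, in temporal order.
#' @param noise_sd Nominal noise floor in degrees.
#' @param spacing_s Gap between consecutive events (edge to edge).
#' @param duration_s Duration of each event.
#' @param start_s Onset of the first event.
#' @param amp_nf Named numeric vector of amplitudes in noise-floor units.
#' @return A data frame usable as `event_plan` in [generate_tail_trace()].
#' @export
tail_event_plan <- function(types, noise_sd = 1.5, spacing_s = 12,
                            duration_s = 0.6, start_s = 5,
                            amp_nf = c(swim = 7, right_flip = 9,
                                       left_flip = 9, struggle = 18)) {
  onsets <- start_s + (seq_along(types) - 1) * (duration_s + spacing_s)
  data.frame(type = types, onset_s = onsets, duration_s = duration_s,
             amplitude_deg = noise_sd * unname(amp_nf[types]))
}

#' Generate a toy brain atlas of nested region and neurotransmitter masks
#'
#' Stands in for the full Z-brain/mapZebrain mask collections: `n_regions`
#' disjoint cuboid base regions are laid out on a reference grid with
#' 1 x 1 x 2 um voxel semantics, and each base region receives strict
#' neurotransmitter-class submasks (random disjoint voxel subsets at the
#' requested fractions). Regions are tagged forebrain/midbrain/hindbrain
#' by their position along the long (y) axis.
#'
#' @param shape_voxels Grid shape (x, y, z) in voxels; the default
#'   120 x 240 x 60 keeps the 75-voxel neuron cube and 12-um
#'   downsampling exercised at small scale.
#' @param n_regions Number of disjoint base regions.
#' @param neurotransmitter_fraction Named per-class voxel fractions; the
#'   classes partition at most the whole region (sum must be <= 1).
#' @param voxel_size_um Physical voxel size.
#' @param margin Voxel margin between regions and around the volume edge.
#' @param seed Integer seed.
#' @return Object of class `toy_atlas`: `grid` (a [reference_grid()]),
#'   `labels` (integer array, 0 = background), `masks` (named list of
#'   linear voxel indices, base regions and `<region>.<class>` submasks)
#'   and `manifest` (name, parent, class, division, n_voxels).
#' @export
generate_toy_atlas <- function(shape_voxels = c(120, 240, 60),
                               n_regions = 10,
                               neurotransmitter_fraction =
                                 c(gad1b = 0.3, vglut2a = 0.3, chata = 0.2),
                               voxel_size_um = c(1, 1, 2),
                               margin = 4, seed = 1L) {
  stopifnot(n_regions >= 1, all(shape_voxels >= 4),
            sum(neurotransmitter_fraction) <= 1,
            all(neurotransmitter_fraction >= 0))
  set.seed(seed)
  grid <- reference_grid(shape_voxels, voxel_size_um)
  labels <- array(0L, shape_voxels)
  # lay regions along y in nrow x ncol tiles
  ncol_t <- ceiling(sqrt(n_regions))
  nrow_t <- ceiling(n_regions / ncol_t)
  xs <- tile_bounds(shape_voxels[1], ncol_t, margin)
  ys <- tile_bounds(shape_voxels[2], nrow_t, margin)
  masks <- list()
  man <- list()
  k <- 0L
  for (iy in seq_len(nrow_t)) for (ix in seq_len(ncol_t)) {
    if (k >= n_regions) break
    k <- k + 1L
    name <- sprintf("region%02d", k)
    rng_x <- xs[[ix]]; rng_y <- ys[[iy]]
    rng_z <- c(margin + 1L, shape_voxels[3] - margin)
    if (n_regions == 1) {                     # single region spans volume
      rng_x <- c(1L, shape_voxels[1])
      rng_y <- c(1L, shape_voxels[2])
      rng_z <- c(1L, shape_voxels[3])
    }
    vox <- as.vector(
      outer(outer(rng_x[1]:rng_x[2],
                  (rng_y[1]:rng_y[2] - 1L) * shape_voxels[1], `+`),
            (rng_z[1]:rng_z[2] - 1L) * shape_voxels[1] * shape_voxels[2],
            `+`))
    labels[vox] <- k
    masks[[name]] <- sort(vox)
    frac_y <- (mean(rng_y) - 0.5) / shape_voxels[2]
    division <- if (frac_y < 1 / 3) "forebrain"
      else if (frac_y < 2 / 3) "midbrain" else "hindbrain"
    man[[length(man) + 1L]] <- data.frame(
      name = name, parent = NA_character_, class = "base",
      division = division, n_voxels = length(vox))
    # neurotransmitter submasks: disjoint random subsets
    pool <- sample(masks[[name]])
    off <- 0L
    for (cls in names(neurotransmitter_fraction)) {
      nv <- floor(neurotransmitter_fraction[[cls]] * length(pool))
      if (nv < 1) next
      sub <- sort(pool[(off + 1L):(off + nv)])
      off <- off + nv
      sname <- paste0(name, ".", cls)
      masks[[sname]] <- sub
      man[[length(man) + 1L]] <- data.frame(
        name = sname, parent = name, class = cls,
        division = division, n_voxels = nv)
    }
  }
  structure(list(grid = grid, labels = labels, masks = masks,
                 manifest = do.call(rbind, man)),
            class = "toy_atlas")
}

# Split 1..extent into n tiles with a margin between and around them.
tile_bounds <- function(extent, n, margin) {
  w <- (extent - margin * (n + 1)) %/% n
  stopifnot(w >= 1)
  lapply(seq_len(n), function(i) {
    a <- margin * i + w * (i - 1) + 1L
    c(a, a + w - 1L)
  })
}

#' Render a synthetic free-swimming movie from a trajectory
#'
#' Draws a dark eye blob (the tracked feature of transparent nacre
#' larvae) on a bright noisy background at each trajectory position.
#'
#' @param trajectory_mm Two-column matrix of (x, y) positions in mm,
#'   one row per frame, inside the arena.
#' @param arena_mm Arena side length in mm (square well).
#' @param px_per_mm Spatial scale.
#' @param contrast Intensity drop of the eye blob against the background
#'   (8-bit units); blobs at contrast below 10 are near the tracker's
#'   documented reliability limit.
#' @param bg_level Background intensity.
#' @param noise_sd Background noise s.d.
#' @param frame_rate Frame rate in Hz (recorded in the output).
#' @param seed Integer seed.
#' @return List: `frames` (array h x w x n), `px_per_mm`, `frame_rate`,
#'   `trajectory_mm` (the ground truth).
#' @export
render_freeswim_movie <- function(trajectory_mm, arena_mm = 35,
                                  px_per_mm = 7, contrast = 40,
                                  bg_level = 230, noise_sd = 2,
                                  frame_rate = 40, seed = 1L) {
  traj <- as.matrix(trajectory_mm)
  stopifnot(ncol(traj) == 2)
  if (any(traj < 0 | traj > arena_mm))
    stop("trajectory leaves the arena")
  set.seed(seed)
  side <- ceiling(arena_mm * px_per_mm)
  n <- nrow(traj)
  frames <- array(stats::rnorm(side * side * n, bg_level, noise_sd),
                  c(side, side, n))
  r <- 1L  # blob half-width in px -> 3 x 3 eye cluster
  for (f in seq_len(n)) {
    cx <- max(r + 1L, min(side - r, round(traj[f, 1] * px_per_mm)))
    cy <- max(r + 1L, min(side - r, round(traj[f, 2] * px_per_mm)))
    frames[(cx - r):(cx + r), (cy - r):(cy + r), f] <-
      frames[(cx - r):(cx + r), (cy - r):(cy + r), f] - contrast
  }
  frames[frames < 0] <- 0
  list(frames = frames, px_per_mm = px_per_mm, frame_rate = frame_rate,
       trajectory_mm = traj, arena_mm = arena_mm)
}

#' Render a multiwell-plate background image
#'
#' Bright wells separated by dark painted boundaries, as seen from a
#' camera above a backlit plate; input for [detect_arenas()].
#'
#' @param n_wells_x,n_wells_y Well grid dimensions.
#' @param well_px Well side length in pixels.
#' @param wall_px Boundary thickness in pixels.
#' @param bg_level,wall_level Intensities of wells and walls.
#' @param noise_sd Pixel noise s.d.
#' @param seed Integer seed.
#' @return List: `image` (matrix), `wells` (true bounding boxes, one row
#'   per well: x0, x1, y0, y1 in px).
#' @export
render_multiwell_background <- function(n_wells_x = 6, n_wells_y = 4,
                                        well_px = 60, wall_px = 8,
                                        bg_level = 220, wall_level = 30,
                                        noise_sd = 3, seed = 1L) {
  set.seed(seed)
  w <- n_wells_x * well_px + (n_wells_x + 1) * wall_px
  h <- n_wells_y * well_px + (n_wells_y + 1) * wall_px
  img <- matrix(wall_level, w, h)
  wells <- NULL
  for (j in seq_len(n_wells_y)) for (i in seq_len(n_wells_x)) {
    x0 <- wall_px * i + well_px * (i - 1) + 1
    y0 <- wall_px * j + well_px * (j - 1) + 1
    img[x0:(x0 + well_px - 1), y0:(y0 + well_px - 1)] <- bg_level
    wells <- rbind(wells, c(x0 = x0, x1 = x0 + well_px - 1,
                            y0 = y0, y1 = y0 + well_px - 1))
  }
  img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), nrow(img))
  list(image = img, wells = as.data.frame(wells))
}
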