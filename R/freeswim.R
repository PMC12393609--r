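#' Arena layout of a multiwell behavioral plate
#'
#' @param wells Data frame of well bounding boxes (`x0`, `x1`, `y0`,
#'   `y1` in px).
#' @param mm_per_px Spatial scale.
#' @param body_length_mm Approximate larval body length (4.5 mm).
#' @param boundary_factor Thigmotaxis boundary as a multiple of the body
#'   length (1.5, giving the 6.75-mm wall margin).
#' @return Object of class `arena_layout`; `wall_margin_mm` is
#'   `body_length_mm * boundary_factor`.
#' @export
arena_layout <- function(wells, mm_per_px, body_length_mm = 4.5,
                         boundary_factor = 1.5) {
  structure(list(wells = wells, mm_per_px = mm_per_px,
                 body_length_mm = body_length_mm,
                 boundary_factor = boundary_factor,
                 wall_margin_mm = body_length_mm * boundary_factor),
            class = "arena_layout")
}

#' Detect wells in a plate background image
#'
#' The background (maximum projection of the first and last 1-minute
#' frame blocks) is Gaussian-smoothed, thresholded at 1.2 times Otsu's
#' threshold, and the bright connected components are taken as wells.
#' Detection fails loudly when the component count differs from the
#' configured well count.
#'
#' @param background Numeric image matrix (wells bright, painted
#'   boundaries dark).
#' @param n_wells Expected well count.
#' @param mm_per_px Spatial scale.
#' @param sigma Gaussian smoothing sigma in px.
#' @param otsu_mult Multiplier on Otsu's threshold.
#' @param min_area_px Minimum well area.
#' @return An [arena_layout()].
#' @export
detect_arenas <- function(background, n_wells = 24, mm_per_px = 0.14,
                          sigma = 2, otsu_mult = 1.2,
                          min_area_px = 100) {
  img <- background / max(background)
  if (stats::sd(img) < 1e-8)
    stop("arena detection failed: uniform background image")
  sm <- EBImage::gblur(EBImage::Image(img), sigma = sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1)) * otsu_mult
  bw <- sm > thr
  lab <- EBImage::bwlabel(bw)
  tab <- table(lab[lab > 0])
  ids <- as.integer(names(tab)[tab >= min_area_px])
  if (length(ids) != n_wells)
    stop(sprintf(paste0("arena detection found %d candidate wells, ",
                        "expected %d"), length(ids), n_wells))
  m <- EBImage::imageData(lab)
  wells <- do.call(rbind, lapply(ids, function(id) {
    w <- which(m == id, arr.ind = TRUE)
    data.frame(x0 = min(w[, 1]), x1 = max(w[, 1]),
               y0 = min(w[, 2]), y1 = max(w[, 2]))
  }))
  # stable ordering: row-major by well center
  cx <- (wells$x0 + wells$x1) / 2
  cy <- (wells$y0 + wells$y1) / 2
  wells <- wells[order(round(cy / 10), cx), , drop = FALSE]
  rownames(wells) <- NULL
  arena_layout(wells, mm_per_px)
}

#' Track a larva inside one well
#'
#' Per frame, segments pixels darker than the frame's background level
#' by at least `min_contrast` intensity units (the dark eye cluster of a
#' nacre larva), suppresses speckle by morphological opening, and keeps
#' the largest blob within the size bounds. Frames without a qualifying
#' blob are missing and filled from the nearest valid neighbor; more
#' than `max_missing` missing frames flags the trajectory as low
#' quality / low SNR.
#'
#' @param frames Array (x, y, frame) cropped to the well.
#' @param mm_per_px Spatial scale.
#' @param frame_rate Acquisition rate in Hz.
#' @param min_contrast Required intensity contrast (10).
#' @param min_area_px,max_area_px Blob area bounds (eye cluster is
#'   ~9-15 px at 0.14 mm/px).
#' @param open_size Structuring-element size for the morphological
#'   opening (suppresses wall-adjacent speckle); 0 disables.
#' @param max_missing Missing-frame fraction above which the trajectory
#'   is flagged.
#' @return Data frame of class `trajectory`: `frame`, `t_s`, `x_mm`,
#'   `y_mm`, `area_px`, `missing`; attributes `low_quality`,
#'   `frame_rate`, `mm_per_px`.
#' @export
track_larva <- function(frames, mm_per_px, frame_rate,
                        min_contrast = 10, min_area_px = 4,
                        max_area_px = 60, open_size = 3,
                        max_missing = 0.2) {
  n <- dim(frames)[3]
  x <- y <- area <- rep(NA_real_, n)
  kern <- if (open_size > 0) EBImage::makeBrush(open_size, "box") else NULL
  for (f in seq_len(n)) {
    fr <- frames[, , f]
    bg <- stats::median(fr)
    bw <- fr < (bg - min_contrast)
    if (!any(bw)) next
    if (!is.null(kern))
      bw <- EBImage::imageData(EBImage::opening(EBImage::Image(bw * 1),
                                                kern)) > 0.5
    if (!any(bw)) next
    lab <- EBImage::bwlabel(bw)
    tab <- table(lab[lab > 0])
    tab <- tab[tab >= min_area_px & tab <= max_area_px]
    if (!length(tab)) next
    id <- as.integer(names(tab)[which.max(tab)])
    w <- which(EBImage::imageData(lab) == id, arr.ind = TRUE)
    x[f] <- mean(w[, 1]); y[f] <- mean(w[, 2]); area[f] <- nrow(w)
  }
  missing <- is.na(x)
  if (all(missing)) {
    traj <- data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) / frame_rate,
                       x_mm = NA_real_, y_mm = NA_real_,
                       area_px = NA_real_, missing = TRUE)
  } else {
    x <- fill_nans(x); y <- fill_nans(y)
    traj <- data.frame(frame = seq_len(n),
                       t_s = (seq_len(n) - 1) / frame_rate,
                       x_mm = x * mm_per_px, y_mm = y * mm_per_px,
                       area_px = area, missing = missing)
  }
  structure(traj, class = c("trajectory", "data.frame"),
            low_quality = mean(missing) > max_missing,
            frame_rate = frame_rate, mm_per_px = mm_per_px)
}

#' Locomotor metrics of one larva
#'
#' Computes the eight open-field metrics over a gap-filled trajectory,
#' decimated to the analysis rate: total distance (mm), RMS speed
#' (mm/s), percentage of arena explored (visited occupancy bins over
#' total bins), bout rate (Hz), mean inter-bout interval (s), mean bout
#' amplitude (net displacement per bout, mm), active-swimming duration
#' (%) and thigmotaxis (% of time within the wall margin). A bout is a
#' contiguous interval with inter-frame speed above `bout_speed` for at
#' least `bout_min_frames` analysis frames, separated by at least
#' `bout_gap_s` below threshold.
#'
#' @param traj A `trajectory`.
#' @param arena_mm Well side length in mm.
#' @param wall_margin_mm Thigmotaxis boundary distance (6.75 mm).
#' @param grid_mm Occupancy bin size (1.75 mm, 20 x 20 bins per 35-mm
#'   well).
#' @param analysis_hz Analysis frame rate the trajectory is decimated
#'   to (raw ~240 fps video is noise-dominated at 0.14 mm/px).
#' @param bout_speed Speed threshold in mm/s.
#' @param bout_min_frames Minimum above-threshold run length.
#' @param bout_gap_s Minimum below-threshold separation.
#' @return List of class `locomotor_metrics`.
#' @export
compute_metrics <- function(traj, arena_mm = 35, wall_margin_mm = 6.75,
                            grid_mm = 1.75, analysis_hz = 40,
                            bout_speed = 2, bout_min_frames = 3,
                            bout_gap_s = 0.1) {
  if (nrow(traj) == 0 || all(is.na(traj$x_mm)))
    stop("zero-length or all-missing trajectory")
  fr <- attr(traj, "frame_rate")
  dec <- max(1L, round(fr / analysis_hz))
  idx <- seq(1L, nrow(traj), by = dec)
  x <- traj$x_mm[idx]; y <- traj$y_mm[idx]
  dt <- dec / fr
  dx <- diff(x); dy <- diff(y)
  step <- sqrt(dx^2 + dy^2)
  speed <- step / dt
  total_distance <- sum(step)
  rms_speed <- sqrt(mean(speed^2))
  # occupancy grid
  nb <- ceiling(arena_mm / grid_mm)
  bx <- pmin(nb - 1, pmax(0, floor(x / grid_mm)))
  by <- pmin(nb - 1, pmax(0, floor(y / grid_mm)))
  explored_pct <- 100 * length(unique(bx + nb * by)) / nb^2
  # bouts
  active <- speed > bout_speed
  bouts <- find_bouts(active, bout_min_frames,
                      max(1L, round(bout_gap_s / dt)))
  n_bouts <- nrow(bouts)
  duration_s <- (length(x) - 1) * dt
  bout_rate <- n_bouts / duration_s
  ibi <- if (n_bouts > 1)
    mean((bouts$start[-1] - bouts$end[-n_bouts]) * dt) else NA_real_
  amp <- if (n_bouts > 0) mean(vapply(seq_len(n_bouts), function(b) {
    i0 <- bouts$start[b]; i1 <- min(bouts$end[b] + 1L, length(x))
    sqrt((x[i1] - x[i0])^2 + (y[i1] - y[i0])^2)
  }, numeric(1))) else NA_real_
  active_pct <- 100 * sum(bouts$end - bouts$start + 1) / length(speed)
  wall <- pmin(x, arena_mm - x, y, arena_mm - y) < wall_margin_mm
  structure(list(
    total_distance_mm = total_distance,
    rms_speed_mm_s = rms_speed,
    arena_explored_pct = explored_pct,
    bout_rate_hz = bout_rate,
    inter_bout_interval_s = ibi,
    bout_amplitude_mm = amp,
    active_duration_pct = active_pct,
    thigmotaxis_pct = 100 * mean(wall)),
    class = "locomotor_metrics")
}

# contiguous above-threshold runs of >= min_len, merging runs separated
# by fewer than gap_frames below-threshold frames
find_bouts <- function(active, min_len, gap_frames) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # close short gaps first
  short_gap <- !r$values & r$lengths < gap_frames &
    seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
  act <- active
  for (i in which(short_gap)) act[starts[i]:ends[i]] <- TRUE
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Classify locomotor impairment from arena exploration
#'
#' A larva is impaired iff its arena-exploration percentage is strictly
#' below the cutoff (35%); arena exploration is the most
#' ablation-sensitive open-field parameter and the basis of the
#' "CA-deficient" label.
#'
#' @param metrics A `locomotor_metrics` object or a numeric
#'   arena-exploration percentage (vectorized).
#' @param cutoff_pct Exploration cutoff.
#' @return Character vector, `"impaired"` or `"unimpaired"`.
#' @export
classify_impairment <- function(metrics, cutoff_pct = 35) {
  x <- if (inherits(metrics, "locomotor_metrics"))
    metrics$arena_explored_pct else as.numeric(metrics)
  ifelse(x < cutoff_pct, "impaired", "unimpaired")
}

#' Exclude outliers by the scaled-MAD rule
#'
#' Excludes values strictly farther than `k` scaled median absolute
#' deviations (consistency constant 1.4826) from the median. The strict
#' comparison makes the zero-MAD case sane: an all-equal list excludes
#' nothing, while a majority-constant list excludes every value off the
#' median.
#'
#' @param values Numeric vector (at least 3 values).
#' @param k MAD multiplier (3).
#' @return List: `retained`, `excluded_idx`.
#' @export
exclude_outliers <- function(values, k = 3) {
  stopifnot(length(values) >= 3)
  m <- stats::median(values)
  s <- stats::mad(values)
  out <- which(abs(values - m) > k * s)
  list(retained = if (length(out)) values[-out] else values,
       excluded_idx = out)
}
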