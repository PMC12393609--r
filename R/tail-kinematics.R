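#' Tail-angle time series
#'
#' Light container for a single base-relative tail-angle trace.
#' Angles are in degrees, signed: with the head pointing toward -x and
#' image y increasing downward (bottom-view tail camera), positive angle
#' means deflection toward the animal's right. The convention is a
#' package choice; mirroring the skeleton's y-coordinates negates every
#' angle and swaps left/right event labels downstream.
#'
#' @param angle_deg Numeric vector of angles.
#' @param frame_rate_hz Sampling rate.
#' @param baseline_removed,nan_filled Processing provenance flags.
#' @return Object of class `tail_trace`.
#' @export
tail_trace <- function(angle_deg, frame_rate_hz,
                       baseline_removed = FALSE, nan_filled = FALSE) {
  stopifnot(frame_rate_hz > 0)
  if (any(abs(angle_deg) >= 180, na.rm = TRUE))
    stop("|angle| must stay below 180 degrees")
  structure(list(angle_deg = as.numeric(angle_deg),
                 frame_rate_hz = frame_rate_hz,
                 baseline_removed = baseline_removed,
                 nan_filled = nan_filled),
            class = "tail_trace")
}

#' @export
print.tail_trace <- function(x, ...) {
  cat(sprintf("tail_trace: %d samples @ %g Hz (%.1f s)%s%s\n",
              length(x$angle_deg), x$frame_rate_hz,
              length(x$angle_deg) / x$frame_rate_hz,
              if (x$baseline_removed) ", baseline removed" else "",
              if (x$nan_filled) ", nan filled" else ""))
  invisible(x)
}

#' Skeletonize one tail-camera frame
#'
#' Extracts an ordered medial-axis point list for the tail from a
#' grayscale frame. The tail is segmented by intensity (darker or
#' brighter than background per `polarity`), reduced to one medial point
#' per image column (the tail runs roughly along x, head toward -x), and
#' ordered by distance from the base point. Absence of a tail is a valid
#' outcome and yields an empty point set (a nan angle downstream).
#'
#' @param image Numeric matrix (x by y, image intensities).
#' @param roi Optional bounding box `c(x0, x1, y0, y1)` to restrict the
#'   search.
#' @param polarity `"dark"` (tail darker than background) or `"bright"`.
#' @param min_px Minimum number of tail pixels for a detection.
#' @return Two-column matrix of (x, y) points ordered base to tip;
#'   zero rows if the tail is not detected.
#' @export
skeletonize_frame <- function(image, roi = NULL, polarity = "dark",
                              min_px = 20) {
  img <- image
  off <- c(0, 0)
  if (!is.null(roi)) {
    img <- image[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
    off <- c(roi[1] - 1, roi[3] - 1)
  }
  v <- as.vector(img)
  thr <- stats::median(v) + c(dark = -1, bright = 1)[[polarity]] *
    3 * stats::mad(v)
  mask <- if (polarity == "dark") img < thr else img > thr
  if (sum(mask) < min_px) return(matrix(numeric(0), 0, 2,
                                        dimnames = list(NULL, c("x", "y"))))
  # per-x-slice centroid: works on blurred frames where per-pixel
  # thinning fails, as the blur spreads mass symmetrically about the axis
  rows <- which(rowSums(mask) > 0)
  yc <- vapply(rows, function(i) mean(which(mask[i, ])), numeric(1))
  pts <- cbind(x = rows + off[1], y = yc + off[2])
  pts[order(pts[, "x"]), , drop = FALSE]
}

#' Segment angles of a tail skeleton
#'
#' Splits the ordered skeleton points into 8 near-equal-count runs (the
#' first `n %% 8` segments absorb the remainder), fits a cubic to each
#' segment, evaluates it at the segment's x-positions, fits a line to the
#' evaluated curve and returns each line's angle to the x-axis in
#' degrees. Fewer than 16 points yields all-NA segments.
#'
#' @param points Two-column (x, y) matrix ordered base to tip.
#' @param n_segments Number of segments (8).
#' @return Numeric vector of `n_segments` angles in degrees.
#' @export
segment_angles <- function(points, n_segments = 8) {
  n <- nrow(points)
  if (is.null(n) || n < 2 * n_segments)
    return(rep(NA_real_, n_segments))
  sizes <- segment_sizes(n, n_segments)
  idx <- split(seq_len(n), rep(seq_len(n_segments), sizes))
  vapply(idx, function(i) {
    x <- points[i, 1]; y <- points[i, 2]
    if (length(unique(x)) < 2) return(90)        # vertical run
    deg <- min(3, length(unique(x)) - 1)
    fit <- stats::lm(y ~ poly(x, deg, raw = TRUE))
    yhat <- stats::fitted(fit)
    line <- stats::lm(yhat ~ x)
    atan(stats::coef(line)[[2]]) * 180 / pi
  }, numeric(1))
}

# Partition n points into k segments by count; earlier segments absorb
# the remainder (n = 17, k = 8 -> 3,2,2,2,2,2,2,2).
segment_sizes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' Summary tail angle per frame
#'
#' For each frame, averages the skeleton points belonging to segments
#' 4 to 7 and measures the signed slope angle of the line connecting the
#' base point to that mean position. Frames without a skeleton give NA.
#'
#' @param skeletons List of (x, y) point matrices, one per frame.
#' @param base_point Length-2 (x, y) base coordinate in pixels.
#' @param frame_rate_hz Sampling rate of the movie.
#' @return A raw (baseline not removed, NAs unfilled) `tail_trace`.
#' @export
summary_angle <- function(skeletons, base_point, frame_rate_hz) {
  ang <- vapply(skeletons, function(p) {
    n <- nrow(p)
    if (is.null(n) || n < 16) return(NA_real_)
    sizes <- segment_sizes(n, 8L)
    seg <- rep(seq_len(8L), sizes)
    sel <- seg >= 4 & seg <= 7
    mx <- mean(p[sel, 1]); my <- mean(p[sel, 2])
    dx <- mx - base_point[1]; dy <- my - base_point[2]
    atan2(-dy, dx) * 180 / pi
  }, numeric(1))
  structure(list(angle_deg = ang, frame_rate_hz = frame_rate_hz,
                 baseline_removed = FALSE, nan_filled = FALSE),
            class = "tail_trace")
}

#' Replace missing samples by their temporally nearest valid value
#'
#' Each NA is replaced by the nearest non-NA sample; on exact ties the
#' earlier sample wins. An all-NA trace is an error.
#'
#' @param trace A `tail_trace` (or numeric vector).
#' @return Same type as the input, with NAs filled.
#' @export
fill_nans <- function(trace) {
  x <- if (inherits(trace, "tail_trace")) trace$angle_deg else trace
  ok <- which(!is.na(x))
  if (!length(ok)) stop("trace contains no valid samples")
  if (length(ok) < length(x)) {
    pos <- seq_along(x)
    # index of nearest valid sample; findInterval gives the last valid
    # at-or-before each position
    below <- findInterval(pos, ok)
    lo <- ok[pmax(below, 1L)]
    hi <- ok[pmin(below + 1L, length(ok))]
    lo[below == 0L] <- hi[below == 0L]
    nearest <- ifelse(pos - lo <= hi - pos, lo, hi)  # tie -> earlier
    x <- x[nearest]
  }
  if (inherits(trace, "tail_trace")) {
    trace$angle_deg <- x
    trace$nan_filled <- TRUE
    trace
  } else x
}

#' Remove the slow baseline from a tail trace
#'
#' Subtracts a dynamic baseline estimated for every sample from a
#' centered (bidirectional) window of `window_s`. The statistic is the
#' windowed median, robust as long as movement events occupy less than
#' half of any window. For speed at video rates the median is evaluated
#' on a coarse time grid (window/60, at most 1 s apart) and linearly
#' interpolated between grid points; the slow drift it targets is smooth
#' at that scale.
#'
#' @param trace A `tail_trace` (NAs must be filled first).
#' @param window_s Bidirectional window length in seconds.
#' @return The baseline-corrected `tail_trace`.
#' @export
remove_baseline <- function(trace, window_s = 60) {
  stopifnot(inherits(trace, "tail_trace"))
  x <- trace$angle_deg
  if (anyNA(x)) stop("fill NAs before baseline removal")
  fs <- trace$frame_rate_hz
  trace$angle_deg <- x - running_stat(x, fs, window_s, stats::median)
  trace$baseline_removed <- TRUE
  trace
}

# Centered running statistic on a coarse grid, linearly interpolated.
# Near the trace ends the window is truncated. Each window's value is
# anchored at the position where a linear trend equals that statistic
# of the window (the midpoint for the median, the anchor_q position for
# a quantile), and the baseline is extended linearly beyond the
# first/last anchors — so a pure ramp is removed exactly, including at
# the trace edges.
running_stat <- function(x, fs, window_s, stat, grid_s = NULL,
                         anchor_q = 0.5, ...) {
  n <- length(x)
  half <- round(window_s * fs / 2)
  if (is.null(grid_s)) grid_s <- min(1, window_s / 60)
  step <- max(1L, round(grid_s * fs))
  centers <- unique(c(seq(1L, n, by = step), n))
  lo <- pmax(1L, centers - half)
  hi <- pmin(n, centers + half)
  anchors <- lo + anchor_q * (hi - lo)
  vals <- vapply(seq_along(centers), function(j) {
    stat(x[lo[j]:hi[j]], ...)
  }, numeric(1))
  keep <- !duplicated(anchors)
  anchors <- anchors[keep]; vals <- vals[keep]
  if (length(anchors) == 1L) return(rep(vals, n))
  out <- stats::approx(anchors, vals, xout = seq_len(n), rule = 2)$y
  m <- length(anchors)
  left <- seq_len(n) < anchors[1]
  if (any(left)) {
    sl <- (vals[2] - vals[1]) / (anchors[2] - anchors[1])
    out[left] <- vals[1] + sl * (which(left) - anchors[1])
  }
  right <- seq_len(n) > anchors[m]
  if (any(right)) {
    sl <- (vals[m] - vals[m - 1]) / (anchors[m] - anchors[m - 1])
    out[right] <- vals[m] + sl * (which(right) - anchors[m])
  }
  out
}

#' Resample a tail trace to the imaging rate by outlier-trimmed maximum
#'
#' Plain interpolation at 1 Hz flattens brief tail beats, so each target
#' bin instead reports its maximum absolute angle after discarding
#' samples above the within-bin 90th percentile of |angle| (linear
#' interpolation between order statistics). The sign of the selected
#' sample is retained. Bins where trimming would discard everything keep
#' all samples; single-sample bins pass through.
#'
#' @param trace A `tail_trace`.
#' @param target_hz Output rate (the imaging rate).
#' @param outlier_q Trimming quantile on |angle|.
#' @return A `tail_trace` at `target_hz`.
#' @export
resample_to_imaging <- function(trace, target_hz = 1, outlier_q = 0.90) {
  stopifnot(inherits(trace, "tail_trace"),
            trace$frame_rate_hz >= target_hz)
  x <- trace$angle_deg
  n <- length(x)
  tt <- (seq_len(n) - 1) / trace$frame_rate_hz
  bin <- floor(tt * target_hz)
  out <- vapply(split(x, bin), function(v) {
    a <- abs(v)
    if (length(v) > 1) {
      thr <- stats::quantile(a, outlier_q, type = 7, names = FALSE)
      keep <- a <= thr
      if (any(keep)) { v <- v[keep]; a <- a[keep] }
    }
    v[which.max(a)]
  }, numeric(1))
  structure(list(angle_deg = unname(out), frame_rate_hz = target_hz,
                 baseline_removed = trace$baseline_removed,
                 nan_filled = trace$nan_filled),
            class = "tail_trace")
}
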