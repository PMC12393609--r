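#' Noise floor of a tail trace
#'
#' Root-mean-square of the (absolute) baseline-corrected tail angle,
#' computed once over the whole recording. All event thresholds are
#' expressed in multiples of this value.
#'
#' @param trace A baseline-corrected `tail_trace` (or numeric vector).
#' @return The noise floor in degrees.
#' @export
noise_floor <- function(trace) {
  x <- if (inherits(trace, "tail_trace")) trace$angle_deg else trace
  sqrt(mean(x^2))
}

#' Detect raw tail-swing events
#'
#' A tail-swing event must contain at least one peak of |angle| more than
#' three times the noise floor with peak prominence above the noise
#' floor. Event extent runs from the last pre-peak crossing of 1x the
#' noise floor to the first post-peak crossing, so adjacent events never
#' overlap; peaks sharing one supra-floor excursion form one event.
#'
#' @param trace Baseline-corrected `tail_trace`.
#' @param nf Noise floor from [noise_floor()]; recomputed when `NULL`.
#' @param peak_k Peak-height threshold in noise-floor units.
#' @return Data frame of events: `onset_s`, `offset_s`, `peak_deg`,
#'   `prominence_deg` (of the tallest qualifying peak).
#' @export
detect_events <- function(trace, nf = NULL, peak_k = 3) {
  stopifnot(inherits(trace, "tail_trace"))
  if (is.null(nf)) nf <- noise_floor(trace)
  if (nf <= 0) stop("degenerate trace: noise floor is zero")
  x <- abs(trace$angle_deg)
  fs <- trace$frame_rate_hz
  above <- x > nf
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]
  if (!nrow(runs))
    return(empty_event_table())
  pk <- find_peaks(x, min_height = peak_k * nf, min_prom = nf)
  if (!nrow(pk))
    return(empty_event_table())
  run_of_peak <- findInterval(pk$index, runs[, 1])
  keep_run <- sort(unique(run_of_peak[pk$index <= runs[run_of_peak, 2]]))
  if (!length(keep_run))
    return(empty_event_table())
  ev <- data.frame(
    onset_s = (runs[keep_run, 1] - 1) / fs,
    offset_s = (runs[keep_run, 2] - 1) / fs)
  ev$peak_deg <- NA_real_; ev$prominence_deg <- NA_real_
  for (i in seq_along(keep_run)) {
    sel <- run_of_peak == keep_run[i] & pk$index <= runs[run_of_peak, 2]
    j <- which.max(pk$height[sel])
    ev$peak_deg[i] <- pk$height[sel][j]
    ev$prominence_deg[i] <- pk$prominence[sel][j]
  }
  ev
}

empty_event_table <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             peak_deg = numeric(0), prominence_deg = numeric(0))
}

# Local maxima of x above min_height whose topographic prominence
# exceeds min_prom. Prominence: height minus the higher of the two
# saddle minima toward the nearest taller sample on each side.
find_peaks <- function(x, min_height = -Inf, min_prom = 0) {
  n <- length(x)
  if (n < 3)
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  core <- x[2:(n - 1)]
  cand <- which(core >= x[1:(n - 2)] & core > x[3:n] &
                  core > min_height) + 1L
  if (!length(cand))
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    l <- i - 1L; lmin <- h
    while (l >= 1L && x[l] <= h) { if (x[l] < lmin) lmin <- x[l]; l <- l - 1L }
    if (l < 1L) lmin <- min(x[1:i])
    r <- i + 1L; rmin <- h
    while (r <= n && x[r] <= h) { if (x[r] < rmin) rmin <- x[r]; r <- r + 1L }
    if (r > n) rmin <- min(x[i:n])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom > min_prom
  data.frame(index = cand[keep], height = x[cand[keep]],
             prominence = prom[keep])
}

#' Merge events separated by short gaps
#'
#' Events whose inter-event gap (offset to next onset) is strictly less
#' than `gap_s` are merged; merging is transitive along chains.
#'
#' @param events Event table from [detect_events()].
#' @param gap_s Minimum gap that keeps events separate (2 s).
#' @return Merged event table (peak columns keep the larger peak).
#' @export
merge_events <- function(events, gap_s = 2) {
  if (nrow(events) < 2) return(events)
  ev <- events[order(events$onset_s), , drop = FALSE]
  gap <- ev$onset_s[-1] - ev$offset_s[-nrow(ev)]
  grp <- cumsum(c(1, as.integer(gap >= gap_s)))
  out <- do.call(rbind, lapply(split(ev, grp), function(g) {
    j <- which.max(g$peak_deg)
    data.frame(onset_s = min(g$onset_s), offset_s = max(g$offset_s),
               peak_deg = g$peak_deg[j],
               prominence_deg = g$prominence_deg[j])
  }))
  rownames(out) <- NULL
  out
}

#' Classify one tail-swing event
#'
#' Struggle: both the positive and the negative extreme exceed
#' `struggle_k` times the noise floor (bidirectional large swings,
#' about 45 degrees for a typical ~4.5-degree noise floor). Otherwise
#' the sums of samples whose |angle| exceeds `flip_floor_k` times the
#' noise floor decide: right flip when the positive sum is more than
#' `flip_ratio` times the absolute negative sum, left flip mirrored;
#' a one-sided event with an empty opposite sum counts as an infinite
#' ratio, hence a flip. Everything else is a swim.
#'
#' @param trace Baseline-corrected `tail_trace`.
#' @param onset_s,offset_s Event extent in seconds.
#' @param nf Noise floor.
#' @param struggle_k,flip_ratio,flip_floor_k Classifier thresholds.
#' @return One of `"swim"`, `"left_flip"`, `"right_flip"`, `"struggle"`.
#' @export
classify_event <- function(trace, onset_s, offset_s, nf,
                           struggle_k = 10, flip_ratio = 20,
                           flip_floor_k = 3) {
  fs <- trace$frame_rate_hz
  i0 <- max(1L, round(onset_s * fs) + 1L)
  i1 <- min(length(trace$angle_deg), round(offset_s * fs) + 1L)
  v <- trace$angle_deg[i0:i1]
  if (max(v) > struggle_k * nf && abs(min(v)) > struggle_k * nf)
    return("struggle")
  big <- v[abs(v) > flip_floor_k * nf]
  pos <- sum(big[big > 0])
  neg <- abs(sum(big[big < 0]))
  if (pos > 0 && (neg == 0 || pos > flip_ratio * neg)) return("right_flip")
  if (neg > 0 && (pos == 0 || neg > flip_ratio * pos)) return("left_flip")
  "swim"
}

#' Detect, merge and classify all tail-swing events of a trace
#'
#' Convenience wrapper running [noise_floor()], [detect_events()],
#' [merge_events()] and [classify_event()] in the standard order.
#'
#' @param trace Baseline-corrected `tail_trace`.
#' @param gap_s Merge gap.
#' @param peak_k,struggle_k,flip_ratio,flip_floor_k Thresholds.
#' @return Event table with a `type` column; noise floor in
#'   `attr(, "noise_floor")`.
#' @export
detect_tail_events <- function(trace, gap_s = 2, peak_k = 3,
                               struggle_k = 10, flip_ratio = 20,
                               flip_floor_k = 3) {
  nf <- noise_floor(trace)
  ev <- merge_events(detect_events(trace, nf, peak_k), gap_s)
  ev$type <- if (nrow(ev)) vapply(seq_len(nrow(ev)), function(i)
    classify_event(trace, ev$onset_s[i], ev$offset_s[i], nf,
                   struggle_k, flip_ratio, flip_floor_k),
    character(1)) else character(0)
  attr(ev, "noise_floor") <- nf
  ev
}

#' Summarize tail-swing events of one larva
#'
#' Per-type event counts, total durations and cumulative |angle| sums
#' over event samples, plus the whole-trace cumulative tail-swing angle
#' (sum of |angle| over all samples).
#'
#' @param events Classified event table (with `type`).
#' @param trace The baseline-corrected `tail_trace`.
#' @return List of class `event_summary`: `counts`, `duration_s`,
#'   `cum_angle_deg` (all named by type) and `cum_trace_deg`.
#' @export
summarize_events <- function(events, trace) {
  types <- c("swim", "left_flip", "right_flip", "struggle")
  fs <- trace$frame_rate_hz
  counts <- stats::setNames(numeric(4), types)
  dur <- counts; cum <- counts
  for (i in seq_len(nrow(events))) {
    ty <- events$type[i]
    counts[ty] <- counts[ty] + 1
    dur[ty] <- dur[ty] + events$offset_s[i] - events$onset_s[i]
    i0 <- max(1L, round(events$onset_s[i] * fs) + 1L)
    i1 <- min(length(trace$angle_deg), round(events$offset_s[i] * fs) + 1L)
    cum[ty] <- cum[ty] + sum(abs(trace$angle_deg[i0:i1]))
  }
  structure(list(counts = counts, duration_s = dur, cum_angle_deg = cum,
                 cum_trace_deg = sum(abs(trace$angle_deg))),
            class = "event_summary")
}
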