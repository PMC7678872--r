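#' Detect intensity peaks in a single square trace
#'
#' A release event shows up as a spike in the square's intensity trace. A
#' frame is called a peak iff it is a local maximum of the trace, its height
#' above a rolling-median baseline exceeds `k_sigma` times a robust noise sd
#' (median absolute deviation of the baseline-subtracted trace, scaled by
#' 1.4826), and it lies at least `min_separation_frames` frames away from any
#' larger accepted peak. Amplitude is the trace value minus the baseline at
#' the peak frame.
#'
#' @param trace Numeric vector, one mean intensity per frame; all values
#'   must be finite.
#' @param baseline_window_frames Odd window length of the rolling median
#'   baseline (default 21 frames, about 1.9 s at 90 ms/frame).
#' @param k_sigma Detection threshold in robust noise sd units (default 5).
#' @param min_separation_frames Minimum frame distance between peaks
#'   (default 3); of two close peaks the larger wins.
#' @return Data frame with columns `frame` (0-based), `amplitude`,
#'   `baseline`, ordered by frame.
#' @export
detect_peaks <- function(trace, baseline_window_frames = 21L, k_sigma = 5,
                         min_separation_frames = 3L) {
  if (!is.numeric(trace) || anyNA(trace) || any(!is.finite(trace))) {
    stop("trace must be finite numeric", call. = FALSE)
  }
  n <- length(trace)
  w <- as.integer(baseline_window_frames)
  if (w %% 2L == 0L) w <- w + 1L
  if (n <= w) stop("trace shorter than the baseline window", call. = FALSE)

  baseline <- stats::runmed(trace, w, endrule = "median")
  resid <- trace - baseline
  sigma <- stats::mad(resid)          # 1.4826 * median(|resid - med|)
  thr <- k_sigma * sigma

  # local maxima (ties resolved to the earliest frame of a plateau)
  left <- c(-Inf, trace[-n])
  right <- c(trace[-1], -Inf)
  cand <- which(trace > left & trace >= right & resid > thr)
  if (length(cand) == 0) {
    return(data.frame(frame = integer(), amplitude = numeric(),
                      baseline = numeric()))
  }
  # enforce min separation, larger peaks first (ties: earlier frame)
  ord <- cand[order(-resid[cand], cand)]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_separation_frames)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)
  data.frame(frame = accepted - 1L, amplitude = resid[accepted],
             baseline = baseline[accepted])
}

#' Reject spillover peaks between neighbouring squares
#'
#' Fluorescence from one fusion event bleeds into adjacent grid squares and
#' can produce simultaneous smaller peaks there. A peak is discarded iff one
#' of the up-to-8 neighbouring squares has a peak at the exact same frame
#' with strictly greater amplitude; among equal-amplitude same-frame
#' neighbours the peak in the lower square id survives. Comparisons use the
#' raw peak set, so a peak removed as spillover still suppresses its other
#' neighbours. Same-frame peaks in non-adjacent squares are all kept.
#'
#' @param peaks Data frame with columns `square_id`, `frame`, `amplitude`
#'   (e.g. pooled [detect_peaks()] calls).
#' @param grid The [partition_grid()] defining square adjacency.
#' @param acquisition Optional [acquisition_params()] used to add `time_s`.
#' @return Data frame of surviving events: `event_id`, `square_id`, `frame`,
#'   `time_s` (if acquisition given), `amplitude`.
#' @export
reject_spillover <- function(peaks, grid, acquisition = NULL) {
  stopifnot(inherits(grid, "grid_partition"))
  if (nrow(peaks) > 0 && !all(peaks$square_id %in% grid$squares$id)) {
    stop("peak references an unknown square", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(peaks))
  if (nrow(peaks) > 0) {
    for (f in unique(peaks$frame)) {
      at <- which(peaks$frame == f)
      if (length(at) < 2) next
      for (i in at) {
        nb <- grid$neighbors[[peaks$square_id[i]]]
        others <- at[peaks$square_id[at] %in% nb]
        if (!length(others)) next
        dominated <- any(
          peaks$amplitude[others] > peaks$amplitude[i] |
          (peaks$amplitude[others] == peaks$amplitude[i] &
             peaks$square_id[others] < peaks$square_id[i]))
        if (dominated) keep[i] <- FALSE
      }
    }
  }
  out <- peaks[keep, c("square_id", "frame", "amplitude"), drop = FALSE]
  out <- out[order(out$frame, out$square_id), , drop = FALSE]
  if (!is.null(acquisition)) {
    out$time_s <- out$frame * acquisition$frame_interval_s
    out <- out[, c("square_id", "frame", "time_s", "amplitude")]
  }
  out <- cbind(event_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Full event calling on a movie
#'
#' Convenience wrapper: partitions the cell mask into grid squares, extracts
#' per-square traces, detects peaks per trace and applies spillover
#' rejection.
#'
#' @param movie A [movie_stack()].
#' @param geometry A [cell_geometry()] on the movie's raster (or a logical
#'   mask matrix).
#' @param square_size_px Grid square side (default 10 px).
#' @inheritParams detect_peaks
#' @return Data frame of detected events (`event_id`, `square_id`, `frame`,
#'   `time_s`, `amplitude`), plus the grid as attribute `"grid"`.
#' @export
detect_events <- function(movie, geometry, square_size_px = 10L,
                          baseline_window_frames = 21L, k_sigma = 5,
                          min_separation_frames = 3L) {
  mask <- if (inherits(geometry, "cell_geometry")) geometry$mask else geometry
  grid <- partition_grid(mask, square_size_px)
  traces <- extract_traces(movie, grid)
  calls <- lapply(seq_along(traces$square_id), function(i) {
    p <- detect_peaks(traces$values[i, ], baseline_window_frames, k_sigma,
                      min_separation_frames)
    if (nrow(p)) cbind(square_id = traces$square_id[i], p) else NULL
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls)) {
    calls <- data.frame(square_id = integer(), frame = integer(),
                        amplitude = numeric(), baseline = numeric())
  }
  out <- reject_spillover(calls, grid, movie$acquisition)
  attr(out, "grid") <- grid
  out
}

#' Normalize an event count to a secretion rate
#'
#' The standard unit of single-cell secretion in this assay:
#' `rate = n_events / (area_um2 / 100) / (duration_s / 60)`, i.e. events per
#' 100 um^2 of cell footprint per minute.
#'
#' @param n_events Non-negative event count.
#' @param area_um2 Cell footprint area in um^2 (> 0).
#' @param duration_s Observation time in seconds (> 0).
#' @param condition_label Optional condition label.
#' @return One-row data frame: `condition`, `n_events`, `area_um2`,
#'   `duration_min`, `rate_per_100um2_min`.
#' @examples
#' normalize_rate(6, 100, 60)$rate_per_100um2_min  # 6
#' @export
normalize_rate <- function(n_events, area_um2, duration_s,
                           condition_label = NA_character_) {
  stopifnot(is.numeric(n_events), n_events >= 0)
  stop_if_not_scalar_pos(area_um2, "area_um2")
  stop_if_not_scalar_pos(duration_s, "duration_s")
  data.frame(condition = condition_label, n_events = n_events,
             area_um2 = area_um2, duration_min = duration_s / 60,
             rate_per_100um2_min =
               n_events / (area_um2 / 100) / (duration_s / 60))
}

#' Match detected events to simulation ground truth
#'
#' Benchmark harness: greedy one-to-one matching in which a detection can
#' claim a ground-truth event iff the truth centre lies in the detection's
#' square or one of its 8 neighbours and the onset frames differ by at most
#' `frame_tolerance`. Detections are processed in (frame, square) order and
#' take the closest-in-time unmatched compatible truth event.
#'
#' @param detected Data frame from [detect_events()].
#' @param truth Data frame from [sample_events()].
#' @param grid The [partition_grid()] used for detection.
#' @param frame_tolerance Maximum |frame difference| for a match.
#' @return List with `precision`, `recall`, `f1`, `n_matched`,
#'   `n_detected`, `n_truth` and `no_detections` flag. With no detections,
#'   precision (and f1) are reported as 0 with `no_detections = TRUE`.
#' @export
match_to_truth <- function(detected, truth, grid, frame_tolerance = 2L) {
  n_det <- nrow(detected); n_tru <- nrow(truth)
  if (n_det == 0) {
    return(list(precision = 0, recall = if (n_tru) 0 else 1,
                f1 = 0, n_matched = 0L, n_detected = 0L, n_truth = n_tru,
                no_detections = TRUE))
  }
  truth_sq <- locate_square(grid, truth$x_px, truth$y_px)
  matched_truth <- rep(FALSE, n_tru)
  ord <- order(detected$frame, detected$square_id)
  n_matched <- 0L
  for (i in ord) {
    ok_sq <- truth_sq %in% c(detected$square_id[i],
                             grid$neighbors[[detected$square_id[i]]])
    df <- abs(truth$frame - detected$frame[i])
    cand <- which(!matched_truth & ok_sq & df <= frame_tolerance)
    if (length(cand)) {
      best <- cand[order(df[cand], cand)][1]
      matched_truth[best] <- TRUE
      n_matched <- n_matched + 1L
    }
  }
  precision <- n_matched / n_det
  recall <- if (n_tru) n_matched / n_tru else 1
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_matched = n_matched, n_detected = n_det, n_truth = n_tru,
       no_detections = FALSE)
}
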