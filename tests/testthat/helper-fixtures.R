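# Shared fixtures for the test suite. Everything is generated in code; no
# binary fixtures are stored.

# A small, fast acquisition/geometry setup for unit tests (32 x 32 px).
tiny_geometry <- function() cell_geometry(disc_mask(32, 32, radius_px = 14))

tiny_acquisition <- function() acquisition_params()

# One-step stimulatory protocol of the given duration.
single_step_protocol <- function(glucose = 3, duration_s = 60) {
  protocol(list(protocol_step(glucose, "none", duration_s)), "single step")
}

# Render a noise-free movie containing the given ground-truth events.
render_clean <- function(events, geometry, n_frames,
                         flash = flash_params(), acq = tiny_acquisition()) {
  render_movie(events, geometry, acq, flash, noise_free(), n_frames,
               seed = 1)
}

# Hand-build a ground-truth event table.
make_events <- function(frame, x_px, y_px, amplitude,
                        dt = tiny_acquisition()$frame_interval_s) {
  data.frame(event_id = seq_along(frame),
             step = rep(1L, length(frame)),
             step_label = rep("fix", length(frame)),
             time_s = frame * dt, frame = as.integer(frame),
             x_px = x_px, y_px = y_px, amplitude = amplitude)
}

# Independent brute-force peak finder used as an oracle for detect_peaks():
# literal per-frame check of the three detection conditions, written without
# reusing the implementation's vectorized code path.
oracle_peaks <- function(trace, w = 21, k = 5, min_sep = 3) {
  base <- stats::runmed(trace, w, endrule = "median")
  resid <- trace - base
  sigma <- stats::mad(resid)
  n <- length(trace)
  is_cand <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i == 1) -Inf else trace[i - 1]
    right <- if (i == n) -Inf else trace[i + 1]
    is_cand[i] <- trace[i] > left && trace[i] >= right &&
      resid[i] > k * sigma
  }
  cand <- which(is_cand)
  acc <- integer(0)
  for (i in cand[order(-resid[cand], cand)]) {
    if (all(abs(acc - i) >= min_sep)) acc <- c(acc, i)
  }
  sort(acc) - 1L
}

# Independent brute-force spillover rule: for every peak, scan all other
# peaks for a same-frame strictly-larger (or equal with lower id) neighbour.
oracle_spillover <- function(peaks, grid) {
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    keep[i] <- TRUE
    for (j in seq_len(nrow(peaks))) {
      if (i == j) next
      if (peaks$frame[j] != peaks$frame[i]) next
      if (!peaks$square_id[j] %in% grid$neighbors[[peaks$square_id[i]]]) next
      if (peaks$amplitude[j] > peaks$amplitude[i] ||
          (peaks$amplitude[j] == peaks$amplitude[i] &&
           peaks$square_id[j] < peaks$square_id[i])) {
        keep[i] <- FALSE
      }
    }
  }
  peaks[keep, ]
}
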