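#' Flash appearance parameters
#'
#' A fusion event appears as a sudden flash: a 2-D Gaussian spot that reaches
#' its full peak amplitude within one frame of onset and then decays
#' exponentially as the reporter diffuses away and is quenched. The defaults
#' make a mean-amplitude flash unambiguous against default camera noise
#' (peak 8x the read-noise sd) while its point-spread function
#' (sigma 0.4 um, about 1.4 px) bleeds measurably into adjacent 10x10-px
#' grid squares only for events near square borders.
#'
#' @param amplitude_mean Mean peak intensity of a flash at the event centre
#'   (arbitrary camera units).
#' @param amplitude_cv Coefficient of variation of flash amplitudes.
#' @param decay_tau_s Exponential decay time constant in seconds
#'   (default 0.27 s, i.e. three 90-ms frames).
#' @param psf_sigma_um Gaussian spatial sd of the flash in micrometres.
#' @return A `flash_params` object.
#' @export
flash_params <- function(amplitude_mean = 160, amplitude_cv = 0.3,
                         decay_tau_s = 0.27, psf_sigma_um = 0.4) {
  stop_if_not_scalar_pos(amplitude_mean, "amplitude_mean")
  stop_if_not_scalar_pos(amplitude_cv, "amplitude_cv")
  stop_if_not_scalar_pos(decay_tau_s, "decay_tau_s")
  stop_if_not_scalar_pos(psf_sigma_um, "psf_sigma_um")
  structure(list(amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
                 decay_tau_s = decay_tau_s, psf_sigma_um = psf_sigma_um),
            class = "flash_params")
}

#' Camera noise parameters
#'
#' @param background_level Constant background offset (camera units).
#' @param read_noise_sd Gaussian read noise sd per pixel per frame.
#' @param shot_noise If `TRUE`, the flash signal photon counts are Poisson
#'   distributed around their expected values.
#' @param bleach_rate_per_s Linear fractional decline of the background per
#'   second (photobleaching of membrane-resident reporter).
#' @return A `noise_params` object.
#' @export
noise_params <- function(background_level = 100, read_noise_sd = 20,
                         shot_noise = TRUE, bleach_rate_per_s = 1e-4) {
  stop_if_not_scalar_pos(background_level, "background_level", strict = FALSE)
  stop_if_not_scalar_pos(read_noise_sd, "read_noise_sd", strict = FALSE)
  stop_if_not_scalar_pos(bleach_rate_per_s, "bleach_rate_per_s", strict = FALSE)
  structure(list(background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise),
                 bleach_rate_per_s = bleach_rate_per_s),
            class = "noise_params")
}

#' Sample ground-truth release events under a protocol
#'
#' Draws fusion events as a homogeneous Poisson process within each protocol
#' step: the expected count is `rate * area_um2 / 100 * duration_s / 60`
#' with the step rate given by the dose-response model (washout steps run at
#' the basal inhibited rate, `r_kd` for knockdown cells). Onset times are
#' uniform within the step, positions uniform over cell-mask pixels with
#' sub-pixel jitter, and amplitudes i.i.d. normal with mean
#' `amplitude_mean` and cv `amplitude_cv` (truncated at a small positive
#' floor). Fully deterministic for a fixed seed.
#'
#' @param model A [dose_response_model()].
#' @param protocol A [protocol()].
#' @param geometry A [cell_geometry()]; must have non-zero area.
#' @param acquisition An [acquisition_params()].
#' @param flash A [flash_params()].
#' @param seed Integer RNG seed (required for reproducibility).
#' @return A data frame of ground-truth events with columns `event_id`,
#'   `step`, `step_label`, `time_s`, `frame` (0-based,
#'   `floor(time_s / frame_interval_s)`), `x_px`, `y_px` (continuous
#'   1-based pixel coordinates, x = column, y = row) and `amplitude`.
#' @examples
#' ev <- sample_events(dose_response_model(), protocol_ramp(),
#'                     cell_geometry(disc_mask()), acquisition_params(),
#'                     seed = 1)
#' head(ev)
#' @export
sample_events <- function(model, protocol, geometry, acquisition,
                          flash = flash_params(), seed) {
  stopifnot(inherits(model, "dose_response_model"),
            inherits(protocol, "protocol"),
            inherits(geometry, "cell_geometry"),
            inherits(acquisition, "acquisition_params"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (geometry$area_um2 <= 0) stop("zero-area cell mask", call. = FALSE)

  mask_idx <- which(geometry$mask)           # linear indices of mask pixels
  nr <- geometry$n_rows
  with_seed(seed, {
    t0 <- 0
    pieces <- vector("list", length(protocol$steps))
    for (k in seq_along(protocol$steps)) {
      s <- protocol$steps[[k]]
      rate <- simulated_rate(model, s)
      lambda <- rate * geometry$area_um2 / 100 * s$duration_s / 60
      n <- rpois(1, lambda)
      if (n > 0) {
        times <- sort(t0 + runif(n) * s$duration_s)
        pix <- mask_idx[sample.int(length(mask_idx), n, replace = TRUE)]
        row <- ((pix - 1) %% nr) + 1
        col <- ((pix - 1) %/% nr) + 1
        amp <- pmax(rnorm(n, flash$amplitude_mean,
                          flash$amplitude_cv * flash$amplitude_mean), 1e-6)
        pieces[[k]] <- data.frame(
          step = k, step_label = s$label, time_s = times,
          frame = floor_div(times, acquisition$frame_interval_s),
          x_px = col + runif(n, -0.5, 0.5),
          y_px = row + runif(n, -0.5, 0.5),
          amplitude = amp)
      }
      t0 <- t0 + s$duration_s
    }
    out <- do.call(rbind, pieces)
    if (is.null(out)) {
      out <- data.frame(step = integer(), step_label = character(),
                        time_s = numeric(), frame = integer(),
                        x_px = numeric(), y_px = numeric(),
                        amplitude = numeric())
    }
    out <- cbind(event_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}

#' Render a TIRF movie from ground-truth events
#'
#' Composes, frame by frame, the linear-in-time bleaching background, each
#' event's flash (an isotropic 2-D Gaussian of sd `psf_sigma_um` centred at
#' the event's sub-pixel position, with peak `amplitude` at the onset frame
#' decaying as `exp(-(t - onset) / decay_tau_s)`), optional Poisson shot
#' noise on the flash signal, and Gaussian read noise, then clips to the
#' camera range `[0, 2^bit_depth - 1]`. Intensities stay floating point;
#' quantization to 16-bit integers happens only on TIFF export.
#'
#' @param events Ground-truth event data frame from [sample_events()].
#' @param geometry A [cell_geometry()] (defines the raster size).
#' @param acquisition An [acquisition_params()].
#' @param flash A [flash_params()].
#' @param noise A [noise_params()]; use
#'   `noise_params(background_level = 0, read_noise_sd = 0, shot_noise = FALSE,
#'   bleach_rate_per_s = 0)` for a noise-free render.
#' @param n_frames Number of frames; all events must fall inside
#'   `[0, n_frames * frame_interval_s)`.
#' @param seed Integer RNG seed for the noise draws.
#' @return A `movie_stack`: list with `data` (rows x cols x frames array)
#'   and `acquisition`.
#' @export
render_movie <- function(events, geometry, acquisition,
                         flash = flash_params(), noise = noise_params(),
                         n_frames, seed = NULL) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(acquisition, "acquisition_params"),
            inherits(flash, "flash_params"), inherits(noise, "noise_params"))
  if (!is.numeric(n_frames) || n_frames <= 0) {
    stop("n_frames must be positive", call. = FALSE)
  }
  n_frames <- as.integer(n_frames)
  if (nrow(events) > 0 &&
      any(events$frame < 0 | events$frame >= n_frames)) {
    stop("events fall outside the rendered frame range", call. = FALSE)
  }
  nr <- geometry$n_rows; nc <- geometry$n_cols
  npix <- nr * nc
  dt <- acquisition$frame_interval_s
  maxv <- 2^acquisition$bit_depth - 1

  with_seed(seed, {
    # per-frame background with linear bleaching, floored at zero
    t_s <- (seq_len(n_frames) - 1) * dt
    bgt <- pmax(noise$background_level * (1 - noise$bleach_rate_per_s * t_s), 0)
    movie <- render_base_cpp(npix, n_frames, bgt, noise$read_noise_sd)

    if (nrow(events) > 0) {
      sig_px <- flash$psf_sigma_um / acquisition$pixel_size_um
      half <- ceiling(4 * sig_px)
      # frames rendered per flash: until the decay factor falls below 1e-3
      n_decay <- min(n_frames, ceiling(flash$decay_tau_s / dt * log(1e3)) + 1L)
      idx_all <- vector("list", nrow(events))
      val_all <- vector("list", nrow(events))
      for (i in seq_len(nrow(events))) {
        r0 <- events$y_px[i]; c0 <- events$x_px[i]
        rr <- max(1L, floor(r0 - half)):min(nr, ceiling(r0 + half))
        cc <- max(1L, floor(c0 - half)):min(nc, ceiling(c0 + half))
        gr <- exp(-((rr - r0)^2) / (2 * sig_px^2))
        gc <- exp(-((cc - c0)^2) / (2 * sig_px^2))
        spot <- events$amplitude[i] * outer(gr, gc)
        f0 <- events$frame[i]
        ff <- f0:min(n_frames - 1L, f0 + n_decay - 1L)
        decay <- exp(-(ff - f0) * dt / flash$decay_tau_s)
        pix <- as.vector(outer(rr, (cc - 1) * nr, `+`))     # within-frame linear
        idx_all[[i]] <- as.numeric(outer(pix, ff * npix, `+`))
        val_all[[i]] <- as.vector(outer(as.vector(spot), decay))
      }
      idx <- unlist(idx_all); val <- unlist(val_all)
      # sum contributions of overlapping flashes per (pixel, frame)
      agg <- rowsum(val, idx)
      uidx <- as.numeric(rownames(agg))
      sig <- agg[, 1]
      if (noise$shot_noise) sig <- rpois(length(sig), sig)
      movie[uidx] <- movie[uidx] + sig
    }
    clip_range_cpp(movie, 0, maxv)
    dim(movie) <- c(nr, nc, n_frames)       # attribute only, no copy
    movie_stack(movie, acquisition)
  })
}

#' Movie container
#'
#' @param data Numeric array, rows x cols x frames, intensities >= 0.
#' @param acquisition An [acquisition_params()].
#' @return A `movie_stack` object.
#' @export
movie_stack <- function(data, acquisition) {
  stopifnot(is.array(data), length(dim(data)) == 3L, dim(data)[3] >= 1)
  structure(list(data = data, acquisition = acquisition),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("movie: %d x %d px, %d frames (%.1f s)\n", d[1], d[2], d[3],
              d[3] * x$acquisition$frame_interval_s))
  invisible(x)
}

#' Noise parameters for an ideal (noise- and background-free) render
#'
#' @return A [noise_params()] object with zero background, zero read noise,
#'   no shot noise and no bleaching.
#' @export
noise_free <- function() {
  noise_params(background_level = 0, read_noise_sd = 0,
               shot_noise = FALSE, bleach_rate_per_s = 0)
}
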