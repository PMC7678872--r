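#' Camera acquisition parameters
#'
#' Bundles the acquisition metadata every stage of the pipeline needs to
#' convert between pixels and micrometres and between frames and seconds.
#' Defaults correspond to a TIRF setup with a 100x objective and a CCD camera
#' in 4x-binned mode: 0.277 um per (binned) pixel and 90 ms exposure with
#' continuous streaming, i.e. 90 ms per frame.
#'
#' @param pixel_size_um Length of one pixel side in micrometres (> 0).
#' @param frame_interval_s Time between consecutive frames in seconds (> 0).
#' @param bit_depth Camera bit depth; intensities live in
#'   `[0, 2^bit_depth - 1]`.
#' @return An object of class `acquisition_params`.
#' @examples
#' acquisition_params()
#' @export
acquisition_params <- function(pixel_size_um = 0.277,
                               frame_interval_s = 0.09,
                               bit_depth = 16L) {
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  stopifnot(bit_depth >= 1, bit_depth <= 32)
  structure(
    list(pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s,
         bit_depth = as.integer(bit_depth)),
    class = "acquisition_params")
}

#' Cell footprint geometry
#'
#' The binary footprint of the analysed cell on the pixel raster, together
#' with its surface area. Area is defined as the number of mask pixels times
#' the pixel area; event rates are later normalized to this area.
#'
#' @param mask Logical (or 0/1) matrix, `TRUE` inside the cell footprint.
#'   Must contain at least one `TRUE` pixel.
#' @param pixel_size_um Pixel size in micrometres.
#' @return An object of class `cell_geometry` with fields `mask`, `n_rows`,
#'   `n_cols`, `pixel_size_um` and `area_um2`.
#' @examples
#' geom <- cell_geometry(disc_mask(64, 64, radius_px = 30))
#' geom$area_um2
#' @export
cell_geometry <- function(mask, pixel_size_um = 0.277) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  if (!any(mask)) stop("cell mask is empty", call. = FALSE)
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(
    list(mask = mask,
         n_rows = nrow(mask),
         n_cols = ncol(mask),
         pixel_size_um = pixel_size_um,
         area_um2 = sum(mask) * pixel_size_um^2),
    class = "cell_geometry")
}

#' Disc-shaped cell mask
#'
#' Convenience footprint generator: a filled disc, the default geometry used
#' by the simulator (a rounded single alpha cell adhering to the coverslip;
#' radius 30 px at 0.277 um/px gives a footprint of about 215 um^2 inside a
#' 64 x 64 field of view).
#'
#' @param n_rows,n_cols Raster size in pixels.
#' @param radius_px Disc radius in pixels.
#' @param center Disc centre `c(row, col)`; defaults to the raster centre.
#' @return Logical matrix.
#' @export
disc_mask <- function(n_rows = 64L, n_cols = 64L, radius_px = 30,
                      center = NULL) {
  if (is.null(center)) center <- c((n_rows + 1) / 2, (n_cols + 1) / 2)
  r <- matrix(seq_len(n_rows), n_rows, n_cols)
  c_ <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  (r - center[1])^2 + (c_ - center[2])^2 <= radius_px^2
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf("acquisition: %.3f um/px, %.3f s/frame, %d-bit\n",
              x$pixel_size_um, x$frame_interval_s, x$bit_depth))
  invisible(x)
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("cell footprint: %d px on a %d x %d raster, area %.2f um^2\n",
              sum(x$mask), x$n_rows, x$n_cols, x$area_um2))
  invisible(x)
}
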