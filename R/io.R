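#' Read / write multi-page TIFF movies
#'
#' Movies are stored as multi-page single-channel 16-bit grayscale TIFF.
#' Writing quantizes the floating-point intensities to integers (round,
#' clip to the camera range); a write-read round trip of integer-valued
#' data is bit exact. Multi-channel / RGB files are rejected. Non-integer
#' (float) TIFFs are accepted and flagged via the `"non_integer"` attribute.
#'
#' @param path TIFF file path.
#' @param acquisition An [acquisition_params()] attached to the returned
#'   stack (TIFF carries no calibration metadata here).
#' @return `read_movie()`: a [movie_stack()].
#' @export
read_movie <- function(path, acquisition = acquisition_params()) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      stop("failed to read TIFF movie: ", conditionMessage(e),
                           call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, TRUE))) {
    stop("multi-channel / RGB TIFF not supported; expected single-channel",
         call. = FALSE)
  }
  d <- dim(pages[[1]])
  arr <- array(unlist(pages), dim = c(d[1], d[2], length(pages)))
  out <- movie_stack(arr, acquisition)
  attr(out, "non_integer") <- any(arr != round(arr))
  out
}

#' @rdname read_movie
#' @param stack A [movie_stack()].
#' @return `write_movie()`: the path, invisibly.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  maxv <- 2^stack$acquisition$bit_depth - 1
  pages <- lapply(seq_len(dim(stack$data)[3]), function(f) {
    m <- round(stack$data[, , f])
    m[m < 0] <- 0; m[m > maxv] <- maxv
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read / write a binary cell mask as TIFF
#'
#' @param mask Logical matrix.
#' @param path TIFF path.
#' @return `read_mask()`: logical matrix; `write_mask()`: the path.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF((mask != 0) * 1, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) > 2) stop("mask TIFF must be single-channel", call. = FALSE)
  m > 0
}

#' Event table CSV round trip
#'
#' Ground-truth events use the header
#' `event_id,frame,time_s,x_px,y_px,amplitude`; detected events use
#' `event_id,square_id,frame,time_s,amplitude`.
#'
#' @param events Event data frame.
#' @param path CSV path.
#' @return The path (writers) or the data frame (reader).
#' @export
write_events_csv <- function(events, path) {
  cols <- intersect(c("event_id", "square_id", "frame", "time_s",
                      "x_px", "y_px", "amplitude"), names(events))
  write.csv(events[, cols, drop = FALSE], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) read.csv(path)

#' @rdname write_events_csv
#' @param records Rate records from [rates_per_condition()].
#' @export
write_rates_csv <- function(records, path) {
  cols <- intersect(c("cell", "condition", "glucose_mM", "treatment",
                      "n_events", "area_um2", "duration_min",
                      "rate_per_100um2_min"), names(records))
  write.csv(records[, cols, drop = FALSE], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Protocol YAML round trip
#'
#' @param protocol A [protocol()].
#' @param path YAML path.
#' @return `read_protocol_yaml()`: a [protocol()].
#' @export
write_protocol_yaml <- function(protocol, path) {
  yaml::write_yaml(list(
    label = protocol$label,
    steps = lapply(protocol$steps, function(s) {
      st <- list(glucose_mM = s$glucose_mM, treatment = s$treatment,
                 duration_s = s$duration_s)
      if (is.finite(s$gka_conc_uM)) st$gka_conc_uM <- s$gka_conc_uM
      st
    })), path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  protocol(lapply(y$steps, function(s) {
    protocol_step(s$glucose_mM, s$treatment, s$duration_s,
                  gka_conc_uM = s$gka_conc_uM %||% NA_real_)
  }), label = y$label %||% "protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a threshold-analysis result as JSON
#'
#' @param result A [detect_threshold()] result.
#' @param path JSON path.
#' @export
write_threshold_json <- function(result, path) {
  jsonlite::write_json(
    list(stimulatory_set = result$stimulatory_set,
         threshold_interval = result$threshold_interval_mM,
         regulated = jsonlite::unbox(result$regulated),
         anova = lapply(result$anova, jsonlite::unbox),
         scheffe = result$scheffe),
    path, digits = NA, na = "null")
  invisible(path)
}
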