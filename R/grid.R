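#' Partition a cell footprint into grid squares
#'
#' Tiles the bounding box of the cell mask with `square_size_px` x
#' `square_size_px` squares anchored at the bounding-box top-left corner
#' (squares on the right/bottom edges may be clipped by the bounding box and
#' are retained as partial squares). Only squares overlapping the mask are
#' kept. An 8-connectivity neighbour map is built among the retained squares;
#' the neighbour relation is symmetric.
#'
#' @param mask Logical matrix, the cell footprint.
#' @param square_size_px Square side in pixels (default 10, >= 2).
#' @return A `grid_partition` object with fields
#'   `squares` (data frame: `id`, `grid_row`, `grid_col`, `row0`, `row1`,
#'   `col0`, `col1`, `n_pixels`), `neighbors` (list of neighbour id vectors,
#'   indexed by id), `square_size_px`, `n_rows`, `n_cols` (raster size) and
#'   `origin` (bounding-box top-left `c(row, col)`).
#' @examples
#' g <- partition_grid(matrix(TRUE, 20, 30))
#' nrow(g$squares)  # 6
#' @export
partition_grid <- function(mask, square_size_px = 10L) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  if (!any(mask)) stop("cell mask is empty", call. = FALSE)
  if (square_size_px < 2) stop("square_size_px must be >= 2", call. = FALSE)
  s <- as.integer(square_size_px)

  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  n_gr <- ceiling((rows[2] - rows[1] + 1) / s)
  n_gc <- ceiling((cols[2] - cols[1] + 1) / s)

  sq <- expand.grid(grid_row = seq_len(n_gr), grid_col = seq_len(n_gc))
  sq$row0 <- rows[1] + (sq$grid_row - 1L) * s
  sq$row1 <- pmin(sq$row0 + s - 1L, rows[2])
  sq$col0 <- cols[1] + (sq$grid_col - 1L) * s
  sq$col1 <- pmin(sq$col0 + s - 1L, cols[2])

  keep <- vapply(seq_len(nrow(sq)), function(i) {
    any(mask[sq$row0[i]:sq$row1[i], sq$col0[i]:sq$col1[i]])
  }, TRUE)
  sq <- sq[keep, , drop = FALSE]
  if (nrow(sq) == 0) stop("no grid square overlaps the mask", call. = FALSE)
  sq$id <- seq_len(nrow(sq))
  sq$n_pixels <- (sq$row1 - sq$row0 + 1L) * (sq$col1 - sq$col0 + 1L)
  sq <- sq[, c("id", "grid_row", "grid_col", "row0", "row1",
               "col0", "col1", "n_pixels")]
  rownames(sq) <- NULL

  neighbors <- lapply(seq_len(nrow(sq)), function(i) {
    adj <- abs(sq$grid_row - sq$grid_row[i]) <= 1 &
      abs(sq$grid_col - sq$grid_col[i]) <= 1
    sq$id[adj & sq$id != sq$id[i]]
  })

  structure(
    list(squares = sq, neighbors = neighbors, square_size_px = s,
         n_rows = nrow(mask), n_cols = ncol(mask),
         origin = c(rows[1], cols[1])),
    class = "grid_partition")
}

#' Locate the grid square containing a point
#'
#' @param grid A [partition_grid()] result.
#' @param x_px,y_px Continuous 1-based pixel coordinates (x = column,
#'   y = row); the point is assigned to the square containing its nearest
#'   pixel centre.
#' @return Vector of square ids (`NA` for points outside all retained
#'   squares).
#' @export
locate_square <- function(grid, x_px, y_px) {
  r <- round(y_px); c_ <- round(x_px)
  s <- grid$square_size_px
  gr <- (r - grid$origin[1]) %/% s + 1
  gc <- (c_ - grid$origin[2]) %/% s + 1
  key <- paste(gr, gc)
  sq_key <- paste(grid$squares$grid_row, grid$squares$grid_col)
  grid$squares$id[match(key, sq_key)]
}

#' Per-square mean intensity traces
#'
#' One trace per retained grid square: the mean over the square's pixels in
#' each frame (mean rather than sum, so clipped partial edge squares remain
#' comparable to full squares).
#'
#' @param movie A [movie_stack()].
#' @param grid A [partition_grid()] built on the same raster.
#' @return A `trace_set`: list with `square_id` and `values`
#'   (squares x frames matrix, rows ordered by square id).
#' @export
extract_traces <- function(movie, grid) {
  stopifnot(inherits(movie, "movie_stack"), inherits(grid, "grid_partition"))
  d <- dim(movie$data)
  if (d[1] != grid$n_rows || d[2] != grid$n_cols) {
    stop("grid raster does not match movie raster", call. = FALSE)
  }
  nr <- d[1]
  sq <- grid$squares
  pix_lists <- lapply(seq_len(nrow(sq)), function(i) {
    rr <- sq$row0[i]:sq$row1[i]
    cc <- sq$col0[i]:sq$col1[i]
    as.integer(outer(rr, (cc - 1L) * nr, `+`)) - 1L   # 0-based for C++
  })
  offsets <- c(0L, cumsum(lengths(pix_lists)))
  values <- square_means_cpp(movie$data, d[1] * d[2], d[3],
                             unlist(pix_lists), offsets)
  structure(list(square_id = sq$id, values = values), class = "trace_set")
}
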