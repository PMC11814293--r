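## Minimal planar raster container.
##
## Values are stored in a matrix with nrow = ny, ncol = nx; row i counts up
## from the southern edge, column j from the western edge. Cells are
## half-open [x, x + cell) x [y, y + cell): a point on a shared edge belongs
## to the cell at its lower-left.

#' Create a planar raster
#'
#' @param values numeric or logical matrix, `nrow = ny`, `ncol = nx`
#'   (row 1 = southernmost row).
#' @param xmin,ymin planar coordinates (m) of the lower-left corner.
#' @param cell cell size in metres (square cells).
#' @return an object of class `mud_raster`.
#' @export
mud_raster <- function(values, xmin = 0, ymin = 0, cell = 100) {
  stopifnot_positive(cell, "cell")
  if (!is.matrix(values)) stop("'values' must be a matrix", call. = FALSE)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cell = cell,
         nx = ncol(values), ny = nrow(values)),
    class = "mud_raster")
}

#' @export
print.mud_raster <- function(x, ...) {
  cat(sprintf("<mud_raster> %d x %d cells of %g m, origin (%g, %g)\n",
              x$nx, x$ny, x$cell, x$xmin, x$ymin))
  invisible(x)
}

raster_extent <- function(r) {
  c(xmin = r$xmin, xmax = r$xmin + r$nx * r$cell,
    ymin = r$ymin, ymax = r$ymin + r$ny * r$cell)
}

## column/row index of points; NA outside the raster
raster_colrow <- function(r, x, y) {
  j <- floor((x - r$xmin) / r$cell) + 1L
  i <- floor((y - r$ymin) / r$cell) + 1L
  bad <- j < 1L | j > r$nx | i < 1L | i > r$ny
  j[bad] <- NA_integer_; i[bad] <- NA_integer_
  list(col = j, row = i)
}

## raster value at point(s); NA outside
raster_value_at <- function(r, x, y) {
  cr <- raster_colrow(r, x, y)
  out <- rep(NA, length(x))
  ok <- !is.na(cr$col)
  out[ok] <- r$values[cbind(cr$row[ok], cr$col[ok])]
  out
}

## cell-centre coordinates, as a data.frame in column-major (row fastest) order
raster_centers <- function(r) {
  xs <- r$xmin + (seq_len(r$nx) - 0.5) * r$cell
  ys <- r$ymin + (seq_len(r$ny) - 0.5) * r$cell
  data.frame(x = rep(xs, each = r$ny), y = rep(ys, times = r$nx))
}

raster_inside <- function(r, x, y) {
  ext <- raster_extent(r)
  x >= ext[["xmin"]] & x < ext[["xmax"]] & y >= ext[["ymin"]] & y < ext[["ymax"]]
}
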