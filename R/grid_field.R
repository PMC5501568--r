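#' Gridded field attribute
#'
#' A `grid_field` holds one attribute (elevation, slope, EMI, ...) on a
#' regular square grid with cell-center registration.  Row 1 of `values`
#' is the southernmost row and column 1 the westernmost, so
#' `values[r, c]` sits at `(origin_x + (c-1)*cell_size,
#' origin_y + (r-1)*cell_size)`.
#'
#' @param values numeric matrix of attribute values, rows south to north.
#' @param origin_x,origin_y coordinates (m) of the lower-left cell center.
#' @param cell_size grid spacing in meters; must be positive.
#' @param nodata logical matrix marking cells with no data, same shape as
#'   `values`, or `NULL` for "wherever `values` is not finite".
#' @param attribute short label for the attribute stored.
#' @param units unit label.
#'
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(values, origin_x = 0, origin_y = 0, cell_size = 10,
                       nodata = NULL, attribute = "value", units = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number", call. = FALSE)
  if (is.null(nodata)) nodata <- !is.finite(values)
  nodata <- as.matrix(nodata)
  if (!identical(dim(values), dim(nodata)))
    stop("values and nodata must have identical shape", call. = FALSE)
  if (any(!is.finite(values[!nodata])))
    stop("non-finite value in a cell not flagged as nodata", call. = FALSE)
  values[nodata] <- NA_real_
  structure(
    list(values = values, origin_x = origin_x, origin_y = origin_y,
         cell_size = cell_size, nodata = nodata,
         attribute = attribute, units = units),
    class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s]: %d x %d cells @ %g m, %d nodata\n",
              x$attribute, x$units, nrow(x$values), ncol(x$values),
              x$cell_size, sum(x$nodata)))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  origin (%g, %g); value range %.4g .. %.4g\n",
              x$origin_x, x$origin_y, rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.grid_field <- function(x) dim(x$values)

#' Cell-center coordinates of a grid
#'
#' @param gf a [grid_field()].
#' @return list with vectors `x` (length ncol) and `y` (length nrow) and
#'   matrices `X`, `Y` of per-cell coordinates.
#' @export
grid_coords <- function(gf) {
  nr <- nrow(gf$values); nc <- ncol(gf$values)
  x <- gf$origin_x + (seq_len(nc) - 1) * gf$cell_size
  y <- gf$origin_y + (seq_len(nr) - 1) * gf$cell_size
  list(x = x, y = y,
       X = matrix(x, nr, nc, byrow = TRUE),
       Y = matrix(y, nr, nc))
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y))
}

#' Point observations of one attribute
#'
#' Irregularly located measurements, e.g. EMI conductivity along sled
#' transects, to be interpolated onto the field grid.
#'
#' @param x,y coordinates in meters.
#' @param value measured values.
#' @param attribute label.
#' @return An object of class `point_samples` (a data frame).
#' @export
point_samples <- function(x, y, value, attribute = "value") {
  if (length(x) != length(y) || length(x) != length(value))
    stop("x, y and value must have equal length", call. = FALSE)
  if (length(x) < 1L)
    stop("at least one point is required", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("point coordinates must be finite", call. = FALSE)
  structure(data.frame(x = x, y = y, value = value),
            attribute = attribute,
            class = c("point_samples", "data.frame"))
}
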