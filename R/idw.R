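#' Inverse distance weighted interpolation to a grid
#'
#' Each grid cell gets \eqn{\sum w_i v_i / \sum w_i} with
#' \eqn{w_i = d_i^{-p}} over the `max_neighbors` nearest observations.
#' A cell closer than 1e-9 m to an observation takes that observation's
#' value exactly.
#'
#' @param points a [point_samples()] object.
#' @param template a [grid_field()] supplying the target geometry; its
#'   nodata mask is carried through.
#' @param power the IDW exponent `p` (> 0); default 2.
#' @param max_neighbors number of nearest points used per cell; default 12.
#' @return A [grid_field()] on the template geometry.
#' @export
idw_interpolate <- function(points, template, power = 2, max_neighbors = 12) {
  if (!inherits(points, "point_samples") || nrow(points) < 1L)
    stop("points must be a non-empty point_samples object", call. = FALSE)
  stopifnot(inherits(template, "grid_field"))
  if (power <= 0) stop("power must be positive", call. = FALSE)
  max_neighbors <- min(as.integer(max_neighbors), nrow(points))
  if (max_neighbors < 1L) stop("max_neighbors must be >= 1", call. = FALSE)

  cc <- grid_coords(template)
  cx <- as.vector(cc$X); cy <- as.vector(cc$Y)
  out <- idw_cpp(cx, cy, points$x, points$y, points$value,
                 power, max_neighbors)
  m <- matrix(out, nrow(template$values), ncol(template$values))
  m[template$nodata] <- NA_real_
  grid_field(m, template$origin_x, template$origin_y, template$cell_size,
             nodata = template$nodata | !is.finite(m),
             attribute = attr(points, "attribute"), units = "")
}
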