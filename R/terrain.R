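#' Terrain attributes from a gridded DEM
#'
#' Slope, aspect and plan curvature are computed from the 3x3
#' Zevenbergen-Thorne quadratic fit around each cell.  With `L` the cell
#' size and the eight neighbours labelled compass-wise (z2 = north,
#' z6 = east, ...), the fitted partial derivatives are
#'
#' \deqn{G = (z6 - z4) / 2L, \quad H = (z2 - z8) / 2L}
#' \deqn{D = ((z4 + z6)/2 - z5) / L^2, \quad
#'       E = ((z2 + z8)/2 - z5) / L^2, \quad
#'       F = (-z1 + z3 + z7 - z9) / 4L^2}
#'
#' giving slope \eqn{100\sqrt{G^2 + H^2}} (percent), aspect
#' \eqn{\mathrm{atan2}(-G, -H)} (the downslope azimuth, degrees clockwise
#' from north in `[0, 360)`), and plan (contour) curvature
#' \eqn{2(DH^2 + EG^2 - FGH)/(G^2 + H^2)} in 1/m.
#'
#' Sign convention: positive plan curvature marks convergent terrain
#' (contours concave in plan, as in closed depressions); set
#' `convergent_positive = FALSE` for the opposite convention.
#'
#' Edge cells use one-sided first differences (implemented by linear
#' extrapolation of the missing neighbour, which also zeroes the edge
#' second difference).  Any cell with a nodata neighbour is nodata in the
#' output.  Cells flatter than `flat_tol` percent slope have no defined
#' aspect (nodata) and zero plan curvature.
#'
#' @param dem a [grid_field()] of elevations in meters, at least 3x3.
#' @param flat_tol slope (percent) below which a cell counts as flat.
#' @param convergent_positive logical; see sign convention above.
#' @return A [grid_field()] of the derived attribute.
#' @name terrain
NULL

zt_coefficients <- function(dem) {
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3L || nc < 3L)
    stop("DEM must be at least 3x3 to derive terrain attributes",
         call. = FALSE)
  L <- dem$cell_size
  # pad by linear extrapolation so central differences at edges reduce
  # to one-sided differences and edge second differences vanish
  p <- matrix(NA_real_, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- v
  p[1L, ] <- 2 * p[2L, ] - p[3L, ]
  p[nr + 2L, ] <- 2 * p[nr + 1L, ] - p[nr, ]
  p[, 1L] <- 2 * p[, 2L] - p[, 3L]
  p[, nc + 2L] <- 2 * p[, nc + 1L] - p[, nc]
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  z5 <- p[ri, ci]
  z2 <- p[ri + 1L, ci];      z8 <- p[ri - 1L, ci]       # N, S
  z6 <- p[ri, ci + 1L];      z4 <- p[ri, ci - 1L]       # E, W
  z3 <- p[ri + 1L, ci + 1L]; z1 <- p[ri + 1L, ci - 1L]  # NE, NW
  z9 <- p[ri - 1L, ci + 1L]; z7 <- p[ri - 1L, ci - 1L]  # SE, SW
  # any nodata cell poisons its full 3x3 neighbourhood
  bad <- !is.finite(z1 + z2 + z3 + z4 + z5 + z6 + z7 + z8 + z9)
  list(
    bad = bad,
    G = (z6 - z4) / (2 * L),
    H = (z2 - z8) / (2 * L),
    D = ((z4 + z6) / 2 - z5) / L^2,
    E = ((z2 + z8) / 2 - z5) / L^2,
    F = (-z1 + z3 + z7 - z9) / (4 * L^2))
}

#' @rdname terrain
#' @export
derive_slope <- function(dem) {
  co <- zt_coefficients(dem)
  s <- 100 * sqrt(co$G^2 + co$H^2)
  s[co$bad] <- NA_real_
  grid_field(s, dem$origin_x, dem$origin_y, dem$cell_size,
             nodata = !is.finite(s), attribute = "slope", units = "%")
}

#' @rdname terrain
#' @export
derive_aspect <- function(dem, flat_tol = 1e-8) {
  co <- zt_coefficients(dem)
  slope_pct <- 100 * sqrt(co$G^2 + co$H^2)
  a <- (atan2(-co$G, -co$H) * 180 / pi) %% 360
  a[slope_pct < flat_tol] <- NA_real_    # aspect undefined on flats
  a[co$bad] <- NA_real_
  grid_field(a, dem$origin_x, dem$origin_y, dem$cell_size,
             nodata = !is.finite(a), attribute = "aspect",
             units = "degrees CW from N")
}

#' @rdname terrain
#' @export
derive_plan_curvature <- function(dem, flat_tol = 1e-8,
                                  convergent_positive = TRUE) {
  co <- zt_coefficients(dem)
  g2 <- co$G^2 + co$H^2
  k <- 2 * (co$D * co$H^2 + co$E * co$G^2 - co$F * co$G * co$H) / g2
  k[100 * sqrt(g2) < flat_tol] <- 0      # flat cells: no contour direction
  if (!convergent_positive) k <- -k
  k[co$bad] <- NA_real_
  grid_field(k, dem$origin_x, dem$origin_y, dem$cell_size,
             nodata = !is.finite(k), attribute = "plan_curvature",
             units = "1/m")
}
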