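# Shared in-code fixtures: everything is generated, nothing read from disk.

# smooth deterministic DEM (sum of gentle sinusoids), no flats
smooth_dem <- function(nr = 12, nc = 15, cell = 10, seed = 1) {
  set.seed(seed)
  x <- (seq_len(nc) - 1) * cell
  y <- (seq_len(nr) - 1) * cell
  a <- runif(3, 0.3, 1)
  z <- outer(y, x, function(yy, xx)
    a[1] * sin(xx / 55 + 0.3) + a[2] * cos(yy / 70 - 0.2) +
      a[3] * sin((xx + yy) / 90) + 0.004 * xx + 0.003 * yy)
  grid_field(z, cell_size = cell, attribute = "elevation", units = "m")
}

# plane z = gx*x + gy*y (+ c)
plane_dem <- function(gx, gy, nr = 8, nc = 9, cell = 10, c0 = 100) {
  x <- (seq_len(nc) - 1) * cell
  y <- (seq_len(nr) - 1) * cell
  grid_field(outer(y, x, function(yy, xx) c0 + gx * xx + gy * yy),
             cell_size = cell, attribute = "elevation", units = "m")
}

# wrap a bare matrix as a normalized feature_matrix (unit scale), with
# dummy location info on an nr x nc grid
as_fm <- function(X, cell = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  rc <- arrayInd(seq_len(n), c(nr, nc))
  structure(
    list(X = X,
         loc = data.frame(row = rc[, 1], col = rc[, 2],
                          x = (rc[, 2] - 1) * cell, y = (rc[, 1] - 1) * cell),
         normalization = list(center = rep(0, ncol(X)),
                              scale = rep(1, ncol(X))),
         geometry = list(dim = c(nr, nc), origin_x = 0, origin_y = 0,
                         cell_size = cell)),
    class = "feature_matrix")
}

# bare codebook on a given lattice from explicit node vectors
as_codebook <- function(codes, rows, cols, topology = "rectangular") {
  codes <- as.matrix(codes)
  structure(
    list(codes = codes, rows = rows, cols = cols, topology = topology,
         lattice = somzones:::lattice_coords(rows, cols, topology),
         k = ncol(codes), init = "manual", seed = NA, trained = TRUE),
    class = "som_codebook")
}

# small synthetic field configuration for fast end-to-end tests
small_cfg <- function(n_potholes = 2, pothole_radius = c(25, 35), ...) {
  synthetic_field_config(nrows = 30, ncols = 40, n_potholes = n_potholes,
                         pothole_radius = pothole_radius, ...)
}

# independent naive greedy farthest-point (the oracle for site spreading)
greedy_oracle <- function(x, y, start, n_total) {
  sel <- start
  for (i in seq_len(n_total - 1)) {
    cand <- setdiff(seq_along(x), sel)
    mind <- vapply(cand, function(j)
      min(sqrt((x[sel] - x[j])^2 + (y[sel] - y[j])^2)), numeric(1))
    sel <- c(sel, cand[which.max(mind)])
  }
  sel
}
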