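test_that("grid_field validates geometry and nodata consistency", {
  expect_error(grid_field(matrix(1, 2, 2), cell_size = 0), "cell_size")
  expect_error(grid_field(matrix(1, 2, 2), nodata = matrix(FALSE, 3, 2)),
               "identical shape")
  m <- matrix(c(1, NA, 3, 4), 2, 2)
  gf <- grid_field(m)                 # non-finite cells auto-masked
  expect_true(gf$nodata[2, 1])
  expect_error(grid_field(m, nodata = matrix(FALSE, 2, 2)), "non-finite")
})

test_that("slope is zero on flats and exact on planes", {
  flat <- plane_dem(0, 0)
  expect_true(all(derive_slope(flat)$values == 0))
  # z = 0.01 x  ->  1 percent slope everywhere (one-sided edges exact too)
  s <- derive_slope(plane_dem(0.01, 0))
  expect_equal(as.vector(s$values), rep(1, length(s$values)), tolerance = 1e-12)
})

test_that("slope matches an independent finite-difference oracle", {
  dem <- smooth_dem(seed = 7)
  s <- derive_slope(dem)$values
  v <- dem$values; L <- dem$cell_size
  nr <- nrow(v); nc <- ncol(v)
  for (r in 2:(nr - 1)) for (cc in 2:(nc - 1)) {
    fx <- (v[r, cc + 1] - v[r, cc - 1]) / (2 * L)
    fy <- (v[r + 1, cc] - v[r - 1, cc]) / (2 * L)
    expect_equal(s[r, cc], 100 * sqrt(fx^2 + fy^2), tolerance = 1e-9)
  }
})

test_that("aspect points downslope, degrees clockwise from north", {
  # dips due south: z increases northward
  expect_equal(as.vector(derive_aspect(plane_dem(0, 0.02))$values),
               rep(180, 72), tolerance = 1e-9)
  # dips due east: z decreases eastward
  expect_equal(as.vector(derive_aspect(plane_dem(-0.02, 0))$values),
               rep(90, 72), tolerance = 1e-9)
  # oracle on a smooth surface, interior cells
  dem <- smooth_dem(seed = 3)
  a <- derive_aspect(dem)$values
  v <- dem$values; L <- dem$cell_size
  for (r in 2:(nrow(v) - 1)) for (cc in 2:(ncol(v) - 1)) {
    fx <- (v[r, cc + 1] - v[r, cc - 1]) / (2 * L)
    fy <- (v[r + 1, cc] - v[r - 1, cc]) / (2 * L)
    expected <- (atan2(-fx, -fy) * 180 / pi) %% 360
    expect_equal((a[r, cc] - expected) %% 360, 0, tolerance = 1e-9)
  }
})

test_that("flat cells have undefined aspect", {
  a <- derive_aspect(plane_dem(0, 0))
  expect_true(all(a$nodata))
})

test_that("plan curvature is zero on planes and 2a on a paraboloid", {
  pc <- derive_plan_curvature(plane_dem(0.01, -0.02))
  expect_equal(as.vector(pc$values), rep(0, 72), tolerance = 1e-12)
  # bowl z = a (x^2 + y^2): convergent everywhere, plan curvature 2a
  # (closed form for the quadratic fit; interior cells, center excluded
  # because the gradient vanishes there)
  a0 <- 0.003
  nr <- 11; nc <- 11; cell <- 10
  x <- ((seq_len(nc)) - 6) * cell; y <- ((seq_len(nr)) - 6) * cell
  bowl <- grid_field(outer(y, x, function(yy, xx) a0 * (xx^2 + yy^2)),
                     cell_size = cell)
  k <- derive_plan_curvature(bowl)$values
  interior <- expand.grid(r = 2:(nr - 1), c = 2:(nc - 1))
  interior <- interior[!(interior$r == 6 & interior$c == 6), ]
  expect_equal(k[as.matrix(interior)],
               rep(2 * a0, nrow(interior)), tolerance = 1e-9)
  # opposite sign convention
  k2 <- derive_plan_curvature(bowl, convergent_positive = FALSE)$values
  expect_equal(k2[2, 3], -k[2, 3])
})

test_that("terrain derivatives are translation- and scale-covariant", {
  dem <- smooth_dem(seed = 11)
  shifted <- grid_field(dem$values + 55, cell_size = dem$cell_size)
  scaled <- grid_field(dem$values * 2.5, cell_size = dem$cell_size)
  expect_equal(derive_slope(shifted)$values, derive_slope(dem)$values)
  expect_equal(derive_aspect(shifted)$values, derive_aspect(dem)$values)
  expect_equal(derive_plan_curvature(shifted)$values,
               derive_plan_curvature(dem)$values)
  expect_equal(derive_slope(scaled)$values, 2.5 * derive_slope(dem)$values)
  expect_equal(derive_aspect(scaled)$values, derive_aspect(dem)$values)
})

test_that("nodata neighbours propagate and small grids error", {
  v <- smooth_dem(nr = 5, nc = 5)$values
  v[3, 3] <- NA
  dem <- grid_field(v)
  s <- derive_slope(dem)
  expect_true(all(s$nodata[2:4, 2:4]))      # all 8 neighbours + itself
  expect_false(s$nodata[1, 1])
  expect_error(derive_slope(grid_field(matrix(1:4, 2, 2))), "3x3")
})

test_that("IDW honours exact hits, symmetry, bounds and a brute-force oracle", {
  tpl <- grid_field(matrix(0, 6, 6), cell_size = 10)
  # exact hit: cell (1,1) is at (0,0)
  pts <- point_samples(c(0, 35), c(0, 5), c(7, 99))
  g <- idw_interpolate(pts, tpl)
  expect_equal(g$values[1, 1], 7)
  # two equidistant points, values 10 and 20 -> 15 for any power
  for (p in c(1, 2, 4)) {
    pts2 <- point_samples(c(10, 30), c(50, 50), c(10, 20))
    g2 <- idw_interpolate(pts2, tpl, power = p)
    expect_equal(g2$values[3, 3], 15)      # cell (3,3) sits at (20, 20)
  }
  # random configuration vs direct double-loop oracle
  set.seed(4)
  pts3 <- point_samples(runif(20, 0, 50), runif(20, 0, 50), rnorm(20))
  g3 <- idw_interpolate(pts3, tpl, power = 2, max_neighbors = 8)
  cc <- grid_coords(tpl)
  for (r in 1:6) for (col in 1:6) {
    d <- sqrt((pts3$x - cc$x[col])^2 + (pts3$y - cc$y[r])^2)
    nb <- order(d)[1:8]
    w <- d[nb]^-2
    expect_equal(g3$values[r, col], sum(w * pts3$value[nb]) / sum(w),
                 tolerance = 1e-9)
  }
  expect_true(all(g3$values >= min(pts3$value) &
                    g3$values <= max(pts3$value)))
  expect_error(idw_interpolate(data.frame(), tpl), "non-empty")
})

test_that("feature matrix assembles the intersection of valid cells", {
  g1 <- grid_field(matrix(1:4, 2, 2))
  g2 <- grid_field(matrix(5:8, 2, 2))
  g3 <- grid_field(matrix(9:12, 2, 2))
  fm <- build_feature_matrix(list(a = g1, b = g2, c = g3))
  expect_equal(dim(fm$X), c(4L, 3L))
  # one nodata cell in one layer drops that row everywhere
  v <- matrix(5:8, 2, 2); v[2, 1] <- NA
  fm2 <- build_feature_matrix(list(a = g1, b = grid_field(v), c = g3))
  expect_equal(nrow(fm2$X), 3L)
  expect_false(any(!is.finite(fm2$X)))
  # geometry mismatch
  expect_error(
    build_feature_matrix(list(a = g1, b = grid_field(matrix(1, 3, 2)))),
    "geometry")
})

test_that("normalization gives exact z-scores and round-trips", {
  set.seed(2)
  layers <- list(a = grid_field(matrix(rnorm(20, 5, 2), 4, 5)),
                 b = grid_field(matrix(runif(20, 0, 9), 4, 5)))
  fm <- build_feature_matrix(layers)
  nf <- normalize_features(fm)
  expect_equal(unname(colMeans(nf$X)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(nf$X, 2, sd)), c(1, 1), tolerance = 1e-9)
  # round trip
  back <- denormalize_features(nf)
  expect_equal(back$X, fm$X, tolerance = 1e-9)
  # already-standardized input is returned unchanged
  Z <- scale(fm$X); attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  fmz <- fm; fmz$X <- Z
  expect_equal(normalize_features(fmz)$X, Z, tolerance = 1e-9)
  # constant column errors with the column named
  fmc <- fm; fmc$X[, 2] <- 3
  expect_error(normalize_features(fmc), "b")
})

test_that("ESRI ASCII grids round-trip values, geometry and nodata", {
  dem <- smooth_dem(nr = 5, nc = 7, seed = 9)
  dem$values[2, 3] <- NA; dem$nodata[2, 3] <- TRUE
  f <- tempfile(fileext = ".asc")
  write_esri_ascii(dem, f)
  back <- read_esri_ascii(f, attribute = "elevation")
  expect_equal(back$values, dem$values, tolerance = 1e-12)
  expect_equal(back$nodata, dem$nodata)
  expect_equal(back$cell_size, 10)
  expect_equal(back$origin_x, dem$origin_x)
  expect_equal(back$origin_y, dem$origin_y)
  # malformed header
  writeLines(c("ncols 3", "bogus"), f)
  expect_error(read_esri_ascii(f), "header")
})
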