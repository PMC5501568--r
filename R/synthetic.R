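#' Configuration for the synthetic pothole field
#'
#' Describes a low-relief glacial-till row-crop field: a gently ridged
#' surface with about 6 m of total relief, closed depressions
#' ("potholes") in the lowlands, a south-facing and a northeast-facing
#' upslope flank, EMI conductivity that rises where elevation falls
#' (wetter, finer-textured lows), and microbial indicators whose
#' pothole/toe-slope zone exceeds the upslope zones by configured
#' multipliers (biomass C x1.6, biomass N x1.75, %TN x1.8, %TC x1.6,
#' extractable organic C x1.3; mass-specific rates inverted, i.e. lowest
#' in the pothole zone).
#'
#' The default 75 x 94 grid at 10 m spacing gives 7050 field locations.
#' EMI base levels and spreads target summary statistics of roughly
#' mean 47 (SD ~14) mS/m for the horizontal coil and 32.6 (SD ~11) for
#' the vertical coil.
#'
#' @param nrows,ncols,cell_size grid shape; 10 m cells by default.
#' @param base_elevation elevation (m) assigned to the lowest cell.
#' @param relief total elevation range in meters (max - min).
#' @param n_potholes number of closed depressions.
#' @param pothole_depth,pothole_radius depth (m) and radius (m) ranges
#'   that depressions are drawn from.
#' @param ridge_asymmetry multiplier on the south-facing facet's gradient
#'   (> 1 makes it steeper than the northeast-facing facet, as toe-slope
#'   fields with an asymmetric ridge typically are).
#' @param noise_sd standard deviation (m) of the smoothed microtopography
#'   noise added to the trend.
#' @param emi list: `hh_base`, `vv_base` (mS/m), `hh_elev_coef`,
#'   `vv_elev_coef` (mS/m per m of elevation, negative), `hh_offset`,
#'   `vv_offset` (per-zone additive shifts, length 3), `hh_noise_sd`,
#'   `vv_noise_sd`, `floor` (truncation for negative draws),
#'   `pass_spacing`, `along_spacing` (sled transect geometry, m).
#' @param indicators data frame with columns `indicator`, `mean`, `cv`
#'   (coefficient of variation) and `zone1_mult` (multiplier applied to
#'   the pothole/toe-slope zone mean; SDs scale with the mean so the CV
#'   is constant across zones).
#' @param null_effects if `TRUE`, all zone multipliers are forced to 1
#'   (a null generator for type-I error calibration).
#' @return An object of class `synthetic_field_config`.
#' @export
synthetic_field_config <- function(
    nrows = 75, ncols = 94, cell_size = 10,
    base_elevation = 309.8, relief = 6,
    n_potholes = 5,
    pothole_depth = c(0.3, 0.5), pothole_radius = c(30, 45),
    ridge_asymmetry = 1.4,
    noise_sd = 0.03,
    emi = list(hh_base = 47, vv_base = 32.6,
               hh_elev_coef = -7.5, vv_elev_coef = -6.0,
               hh_offset = c(12, -5, 0), vv_offset = c(9, -4, 0),
               hh_noise_sd = 4, vv_noise_sd = 3, floor = 0.5,
               pass_spacing = 20, along_spacing = 5),
    indicators = default_indicator_model(),
    null_effects = FALSE) {
  cfg <- list(nrows = as.integer(nrows), ncols = as.integer(ncols),
              cell_size = cell_size, base_elevation = base_elevation,
              relief = relief, n_potholes = as.integer(n_potholes),
              pothole_depth = pothole_depth,
              pothole_radius = pothole_radius,
              ridge_asymmetry = ridge_asymmetry, noise_sd = noise_sd,
              emi = emi, indicators = indicators,
              null_effects = isTRUE(null_effects))
  if (cfg$nrows < 3L || cfg$ncols < 3L)
    stop("grid must be at least 3x3", call. = FALSE)
  if (cfg$relief < 0 || cfg$noise_sd < 0)
    stop("relief and noise_sd must be non-negative", call. = FALSE)
  if (any(cfg$indicators$zone1_mult <= 0) || any(cfg$indicators$cv < 0))
    stop("indicator multipliers must be positive and CVs non-negative",
         call. = FALSE)
  if (cfg$null_effects) cfg$indicators$zone1_mult <- 1
  class(cfg) <- "synthetic_field_config"
  cfg
}

#' @rdname synthetic_field_config
#' @export
default_indicator_model <- function() {
  data.frame(
    indicator = c("eoc", "mbc", "mbn", "tc_pct", "tn_pct",
                  "specific_c_min", "specific_n_min",
                  "nitrate", "ammonium", "n_min", "c_min",
                  "ph", "moisture_gg"),
    mean = c(60, 300, 40, 2.0, 0.17,
             0.030, 0.012,
             10, 5, 15, 8,
             6.5, 0.25),
    cv = c(0.20, 0.20, 0.20, 0.15, 0.15,
           0.20, 0.25,
           0.30, 0.30, 0.30, 0.25,
           0.04, 0.15),
    zone1_mult = c(1.3, 1.6, 1.75, 1.6, 1.8,
                   1 / 1.6, 1 / 1.3,
                   1, 1, 1, 1,
                   1, 1.15))
}

#' Generate the synthetic DEM and its zone truth
#'
#' The trend surface is the soft minimum of two tilted facets — one
#' rising northward (so its flank faces south) and one rising toward the
#' southwest (flank facing northeast) — whose intersection forms a
#' NW-SE ridge.  Gaussian pits are subtracted at randomly chosen
#' low-trend cells, smoothed noise is added, and the result is rescaled
#' so max - min equals the configured relief exactly.
#'
#' Zone truth (by construction): zone 1 = cells inside a pothole's
#' depression or on the low toe slopes; zone 2 = remaining south-facing
#' facet; zone 3 = remaining northeast-facing facet.  A zero-relief
#' configuration yields a constant surface, all of it zone 1.
#'
#' @param cfg a [synthetic_field_config()].
#' @param seed RNG seed.
#' @return list with `dem` (a [grid_field()]) and `truth` (list with
#'   integer matrix `zone` and the pothole table).
#' @export
generate_dem <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_field_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  nr <- cfg$nrows; nc <- cfg$ncols; L <- cfg$cell_size
  x <- (seq_len(nc) - 1) * L; y <- (seq_len(nr) - 1) * L
  U <- matrix(x / max(x), nr, nc, byrow = TRUE)
  V <- matrix(y / max(y), nr, nc)

  fa <- V * cfg$ridge_asymmetry   # rises north: south-facing flank (steeper)
  # rises to the SW with equal physical gradient components, so the
  # flank faces northeast (azimuth 45), well away from the 0/360 wrap
  Lx <- max(x); Ly <- max(y)
  fb <- ((Lx - U * Lx) + (Ly - V * Ly)) / (Lx + Ly)
  temp <- 0.08                     # softmin temperature (ridge rounding)
  z0 <- -temp * log(exp(-fa / temp) + exp(-fb / temp))

  if (cfg$relief == 0) {
    dem <- grid_field(matrix(cfg$base_elevation, nr, nc),
                      cell_size = L, attribute = "elevation", units = "m")
    return(list(dem = dem,
                truth = list(zone = matrix(1L, nr, nc),
                             potholes = NULL)))
  }

  z <- z0 * cfg$relief
  # potholes: pits centred on randomly chosen low-trend cells
  depression <- matrix(0, nr, nc)
  potholes <- NULL
  if (cfg$n_potholes > 0L) {
    low <- which(z0 <= quantile(z0, 0.25))
    ctr <- sample(low, cfg$n_potholes, replace = length(low) < cfg$n_potholes)
    rc <- arrayInd(ctr, c(nr, nc))
    depth <- runif(cfg$n_potholes, cfg$pothole_depth[1], cfg$pothole_depth[2])
    radius <- runif(cfg$n_potholes, cfg$pothole_radius[1],
                    cfg$pothole_radius[2])
    X <- matrix(x, nr, nc, byrow = TRUE); Y <- matrix(y, nr, nc)
    for (j in seq_len(cfg$n_potholes)) {
      d2 <- (X - x[rc[j, 2]])^2 + (Y - y[rc[j, 1]])^2
      depression <- depression + depth[j] * exp(-d2 / (2 * radius[j]^2))
    }
    potholes <- data.frame(x = x[rc[, 2]], y = y[rc[, 1]],
                           depth = depth, radius = radius)
  }
  z <- z - depression
  if (cfg$noise_sd > 0) z <- z + smooth_noise(nr, nc, cfg$noise_sd,
                                              kernel_cells = 5)
  z <- (z - min(z)) / (max(z) - min(z)) * cfg$relief + cfg$base_elevation

  zone <- ifelse(fa < fb, 2L, 3L)
  zone[depression > 0.25 | z0 < quantile(z0, 0.15)] <- 1L
  if (length(unique(as.vector(zone))) < 3L)
    stop("synthetic configuration leaves a zone empty; ",
         "adjust potholes/relief", call. = FALSE)
  list(dem = grid_field(z, cell_size = L, attribute = "elevation",
                        units = "m"),
       truth = list(zone = zone, potholes = potholes))
}

# white noise convolved with a small Gaussian kernel, rescaled to sd
smooth_noise <- function(nr, nc, sd, kernel_cells = 3) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  ks <- seq(-2 * kernel_cells, 2 * kernel_cells)
  kern <- exp(-ks^2 / (2 * kernel_cells^2)); kern <- kern / sum(kern)
  sm <- apply(w, 2, function(col) stats::filter(col, kern, circular = TRUE))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, kern,
                                                   circular = TRUE)))
  sm * sd / stats::sd(as.vector(sm))
}

#' Generate EMI transect observations over the synthetic field
#'
#' Emulates an EMI sled survey: parallel north-south passes
#' `pass_spacing` apart with dense readings every `along_spacing` along
#' track.  Each reading is
#' `base + coef * (elevation - mean elevation) + zone offset + noise`,
#' truncated below at `floor` mS/m, for both coil orientations.
#'
#' @param dem the synthetic DEM.
#' @param truth the zone truth from [generate_dem()].
#' @param cfg a [synthetic_field_config()].
#' @param seed RNG seed.
#' @return list of two [point_samples()]: `hh` and `vv`.
#' @export
generate_emi <- function(dem, truth, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_field_config"),
            inherits(dem, "grid_field"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  e <- cfg$emi
  cc <- grid_coords(dem)
  xmax <- max(cc$x); ymax <- max(cc$y)
  px <- seq(0, xmax, by = e$pass_spacing)
  py <- seq(0, ymax, by = e$along_spacing)
  pts <- expand.grid(y = py, x = px)    # along-track (y) varies fastest
  ri <- pmin(pmax(round(pts$y / dem$cell_size) + 1, 1), nrow(dem$values))
  ci <- pmin(pmax(round(pts$x / dem$cell_size) + 1, 1), ncol(dem$values))
  elev <- dem$values[cbind(ri, ci)]
  zone <- truth$zone[cbind(ri, ci)]
  dz <- elev - mean(dem$values, na.rm = TRUE)
  n <- nrow(pts)
  hh <- pmax(e$hh_base + e$hh_elev_coef * dz + e$hh_offset[zone] +
               rnorm(n, 0, e$hh_noise_sd), e$floor)
  vv <- pmax(e$vv_base + e$vv_elev_coef * dz + e$vv_offset[zone] +
               rnorm(n, 0, e$vv_noise_sd), e$floor)
  list(hh = point_samples(pts$x, pts$y, hh, attribute = "emi_hh"),
       vv = point_samples(pts$x, pts$y, vv, attribute = "emi_vv"))
}

#' Stratified sites straight from the zone truth
#'
#' A shortcut design for simulation studies: `n_per_zone` locations
#' drawn at random within each true zone (no SOM involved), labelled
#' with the zone as cluster id.  The first site of each zone is given
#' the BMU role so the design is accepted wherever a
#' [select_additional_sites()] result is.
#'
#' @param fm a `feature_matrix` over the synthetic grid.
#' @param truth zone truth from [generate_dem()].
#' @param n_per_zone sites per zone (default 12).
#' @param seed RNG seed.
#' @return A `sampling_design`.
#' @export
sites_from_truth <- function(fm, truth, n_per_zone = 12, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  zone <- truth$zone[cbind(fm$loc$row, fm$loc$col)]
  zones <- sort(unique(zone))
  out <- lapply(zones, function(zl) {
    members <- which(zone == zl)
    sel <- sample(members, min(n_per_zone, length(members)))
    data.frame(cluster = zl,
               role = c("BMU", rep("additional", length(sel) - 1L)),
               row = sel, x = fm$loc$x[sel], y = fm$loc$y[sel],
               dist_to_centroid = NA_real_)
  })
  sites <- do.call(rbind, out)
  structure(list(sites = sites, k = length(zones),
                 n_additional = n_per_zone - 1L,
                 sites_total = nrow(sites), shortfall = integer(0)),
            class = "sampling_design")
}

#' Generate a sample table for a sampling design
#'
#' Draws each microbial indicator for each design site from
#' `Normal(zone mean, zone mean * cv)`, where the pothole/toe-slope zone
#' (true zone 1) mean is the base mean times the configured multiplier,
#' and copies the terrain/EMI attributes from the grids at the site.
#'
#' @param truth zone truth from [generate_dem()].
#' @param design a `sampling_design` whose `row` indices refer to `fm`.
#' @param fm the (raw or normalized) `feature_matrix` of the field.
#' @param cfg a [synthetic_field_config()].
#' @param seed RNG seed.
#' @return A sample table (data frame): `sample_id`, `x`, `y`,
#'   `cluster`, `true_zone`, the six landscape attributes, the indicator
#'   set and `mbc_mbn_ratio`.
#' @export
generate_sample_table <- function(truth, design, fm, cfg, seed = 1L) {
  stopifnot(inherits(design, "sampling_design"),
            inherits(fm, "feature_matrix"),
            inherits(cfg, "synthetic_field_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  raw <- denormalize_features(fm)
  s <- design$sites
  zone <- truth$zone[cbind(fm$loc$row[s$row], fm$loc$col[s$row])]
  n <- nrow(s)
  tab <- data.frame(sample_id = seq_len(n), x = s$x, y = s$y,
                    cluster = s$cluster, true_zone = zone)
  attrs <- raw$X[s$row, , drop = FALSE]
  for (j in colnames(attrs)) tab[[j]] <- attrs[, j]
  im <- cfg$indicators
  for (i in seq_len(nrow(im))) {
    mu <- im$mean[i] * ifelse(zone == 1L, im$zone1_mult[i], 1)
    tab[[im$indicator[i]]] <- rnorm(n, mu, mu * im$cv[i])
  }
  if (all(c("mbc", "mbn") %in% names(tab)))
    tab$mbc_mbn_ratio <- tab$mbc / tab$mbn
  tab
}

#' Simulate a complete synthetic field
#'
#' Runs [generate_dem()], derives the terrain layers, runs
#' [generate_emi()] and interpolates both coils to the grid, and
#' assembles the normalized six-attribute feature matrix.
#'
#' @param cfg a [synthetic_field_config()].
#' @param seed RNG seed (offsets are derived from it for each stage).
#' @param idw_power,idw_neighbors IDW parameters.
#' @return list with `dem`, `truth`, `emi_points`, `layers` (named list
#'   of the six grids), `fm` (normalized feature matrix) and
#'   `truth_labels` (zone per feature-matrix row).
#' @export
simulate_field <- function(cfg = synthetic_field_config(), seed = 1L,
                           idw_power = 2, idw_neighbors = 12) {
  g <- generate_dem(cfg, seed = seed)
  emi <- generate_emi(g$dem, g$truth, cfg, seed = seed + 1L)
  layers <- list(
    elevation = g$dem,
    slope = derive_slope(g$dem),
    aspect = derive_aspect(g$dem),
    plan_curvature = derive_plan_curvature(g$dem),
    emi_hh = idw_interpolate(emi$hh, g$dem, idw_power, idw_neighbors),
    emi_vv = idw_interpolate(emi$vv, g$dem, idw_power, idw_neighbors))
  fm <- normalize_features(build_feature_matrix(layers))
  list(dem = g$dem, truth = g$truth, emi_points = emi, layers = layers,
       fm = fm,
       truth_labels = g$truth$zone[cbind(fm$loc$row, fm$loc$col)])
}
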