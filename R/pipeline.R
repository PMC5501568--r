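#' Run the full zone-delineation and site-selection pipeline
#'
#' From a DEM and EMI transects to a sampling design: derive slope,
#' aspect and plan curvature; interpolate both EMI coils to the grid;
#' assemble and normalize the feature matrix; train the SOM; partition
#' the codebook with K-means; and select one best-matching location per
#' cluster plus spatially spread additional sites.
#'
#' @param dem a [grid_field()] of elevation.
#' @param emi_hh,emi_vv [point_samples()] of the two EMI coils.
#' @param k number of clusters (user decision, typically from the
#'   U-matrix).
#' @param n_additional additional sites per cluster (default 11; with
#'   k = 3 the design has 36 sites).
#' @param idw_power,idw_neighbors IDW parameters.
#' @param som_rows,som_cols lattice size (`NULL` = heuristic).
#' @param schedule_scale multiplier on the training schedule length.
#' @param seed single seed driving SOM training and K-means restarts.
#' @return list with `layers`, `fm`, `codebook`, `umatrix`, `model` (the
#'   `cluster_model`) and `design` (the `sampling_design`).
#' @export
run_zone_pipeline <- function(dem, emi_hh, emi_vv, k = 3,
                              n_additional = 11,
                              idw_power = 2, idw_neighbors = 12,
                              som_rows = NULL, som_cols = NULL,
                              schedule_scale = 1, seed = 1L) {
  layers <- list(
    elevation = dem,
    slope = derive_slope(dem),
    aspect = derive_aspect(dem),
    plan_curvature = derive_plan_curvature(dem),
    emi_hh = idw_interpolate(emi_hh, dem, idw_power, idw_neighbors),
    emi_vv = idw_interpolate(emi_vv, dem, idw_power, idw_neighbors))
  fm <- normalize_features(build_feature_matrix(layers))
  cb <- som_codebook(fm, rows = som_rows, cols = som_cols, seed = seed)
  sched <- som_schedule(nrow(fm$X), cb$rows, cb$cols,
                        scale = schedule_scale)
  cb <- som_train(cb, fm, schedule = sched, seed = seed)
  um <- compute_umatrix(cb)
  cm <- cluster_field(cb, fm, k = k, seed = seed)
  design <- select_additional_sites(cm, fm, n_per_cluster = n_additional)
  list(layers = layers, fm = fm, codebook = cb, umatrix = um,
       model = cm, design = design)
}

#' Zone-recovery accuracy against planted truth
#'
#' Fraction of locations whose recovered cluster matches the true zone
#' under the best one-to-one relabelling (all permutations of the
#' smaller label set are tried).
#'
#' @param labels recovered cluster ids.
#' @param truth_labels planted zone ids.
#' @return list with `accuracy` and the best `permutation`
#'   (`permutation[i]` is the truth label matched to cluster `i`).
#' @export
score_zone_recovery <- function(labels, truth_labels) {
  stopifnot(length(labels) == length(truth_labels))
  ks <- sort(unique(labels)); kt <- sort(unique(truth_labels))
  perms <- permutations(kt)
  best <- -Inf; best_p <- NULL
  for (p in perms) {
    names(p) <- as.character(ks[seq_along(p)])
    acc <- mean(p[as.character(labels)] == truth_labels, na.rm = TRUE)
    if (acc > best) { best <- acc; best_p <- p }
  }
  list(accuracy = best, permutation = best_p)
}

permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
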