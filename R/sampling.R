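#' Select the best-matching field location per cluster
#'
#' Within each cluster, the member location whose (normalized) feature
#' vector has the smallest Euclidean distance to the cluster centroid is
#' the cluster's critical sampling site; ties go to the lowest row
#' index.
#'
#' @param cm a [cluster_field()] result.
#' @param fm the matching `feature_matrix`.
#' @return An object of class `sampling_design`: data frame `sites` with
#'   columns `cluster`, `role` (`"BMU"` here), `row` (feature-matrix row
#'   index), `x`, `y`, `dist_to_centroid`; plus `k`, `n_additional = 0`,
#'   `sites_total` and `shortfall`.
#' @export
select_bmu_location <- function(cm, fm) {
  stopifnot(inherits(cm, "cluster_model"), inherits(fm, "feature_matrix"))
  rows <- vapply(seq_len(cm$k), function(cl) {
    members <- which(cm$location_labels == cl)
    d2 <- rowSums((fm$X[members, , drop = FALSE] -
                     matrix(cm$centroids[cl, ], length(members),
                            ncol(fm$X), byrow = TRUE))^2)
    members[which.min(d2)]             # which.min keeps the lowest index
  }, integer(1))
  d <- sqrt(rowSums((fm$X[rows, , drop = FALSE] - cm$centroids)^2))
  sites <- data.frame(cluster = seq_len(cm$k), role = "BMU", row = rows,
                      x = fm$loc$x[rows], y = fm$loc$y[rows],
                      dist_to_centroid = d)
  structure(list(sites = sites, k = cm$k, n_additional = 0L,
                 sites_total = nrow(sites), shortfall = integer(0)),
            class = "sampling_design")
}

#' Add spatially spread sampling sites per cluster
#'
#' Starting from each cluster's best-matching location, repeatedly adds
#' the member whose minimum geographic distance to the already-selected
#' sites is largest (greedy farthest-point selection); ties go to the
#' lowest row index.  With `k` clusters and `n_per_cluster` additional
#' sites each, the design holds `k * (1 + n_per_cluster)` sites when
#' every cluster has enough members; smaller clusters contribute all
#' their members and the shortfall is reported.
#'
#' @param cm a [cluster_field()] result.
#' @param fm the matching `feature_matrix`.
#' @param n_per_cluster additional sites per cluster (>= 0); default 11,
#'   giving 36 sites at k = 3.
#' @return A `sampling_design` (see [select_bmu_location()]) whose
#'   `sites` mix roles `"BMU"` and `"additional"`.
#' @export
select_additional_sites <- function(cm, fm, n_per_cluster = 11) {
  stopifnot(inherits(cm, "cluster_model"), inherits(fm, "feature_matrix"))
  n_per_cluster <- as.integer(n_per_cluster)
  if (n_per_cluster < 0L) stop("n_per_cluster must be >= 0", call. = FALSE)
  base <- select_bmu_location(cm, fm)
  out <- list(); shortfall <- integer(0)
  for (cl in seq_len(cm$k)) {
    members <- which(cm$location_labels == cl)
    bmu_row <- base$sites$row[cl]
    want <- 1L + n_per_cluster
    if (length(members) <= want) {
      if (length(members) < want) {
        shortfall[as.character(cl)] <- want - length(members)
        message("cluster ", cl, " has only ", length(members),
                " members; selecting all (shortfall ",
                want - length(members), ")")
      }
      sel <- c(bmu_row, setdiff(members, bmu_row))
    } else {
      sel <- farthest_point_selection(
        fm$loc$x[members], fm$loc$y[members],
        start = match(bmu_row, members), n_total = want)
      sel <- members[sel]
    }
    role <- c("BMU", rep("additional", length(sel) - 1L))
    out[[cl]] <- data.frame(
      cluster = cl, role = role, row = sel,
      x = fm$loc$x[sel], y = fm$loc$y[sel],
      dist_to_centroid = sqrt(rowSums(
        (fm$X[sel, , drop = FALSE] -
           matrix(cm$centroids[cl, ], length(sel), ncol(fm$X),
                  byrow = TRUE))^2)))
  }
  sites <- do.call(rbind, out)
  structure(list(sites = sites, k = cm$k, n_additional = n_per_cluster,
                 sites_total = nrow(sites), shortfall = shortfall),
            class = "sampling_design")
}

# greedy farthest-point: indices into (x, y), starting from `start`
farthest_point_selection <- function(x, y, start, n_total) {
  n <- length(x)
  sel <- integer(n_total); sel[1L] <- start
  mind <- sqrt((x - x[start])^2 + (y - y[start])^2)
  mind[start] <- -Inf
  for (i in seq_len(n_total - 1L)) {
    nxt <- which.max(mind)             # ties -> lowest index
    sel[i + 1L] <- nxt
    d <- sqrt((x - x[nxt])^2 + (y - y[nxt])^2)
    mind <- pmin(mind, d)
    mind[nxt] <- -Inf
  }
  sel
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf(
    "<sampling_design> %d sites (%d clusters x (1 BMU + %d additional))\n",
    x$sites_total, x$k, x$n_additional))
  if (length(x$shortfall))
    cat("  shortfall in cluster(s):",
        paste(names(x$shortfall), collapse = ", "), "\n")
  invisible(x)
}

#' Write a sampling design to CSV
#'
#' @param design a `sampling_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "sampling_design"))
  write.csv(design$sites, path, row.names = FALSE)
  invisible(path)
}

#' Cluster labels as a raster
#'
#' Maps location labels back onto the field grid (nodata where a cell
#' was excluded from the feature matrix) for export with
#' [write_esri_ascii()].
#'
#' @param cm a [cluster_field()] result.
#' @param fm the matching `feature_matrix`.
#' @return A [grid_field()] of integer labels.
#' @export
cluster_raster <- function(cm, fm) {
  stopifnot(inherits(cm, "cluster_model"), inherits(fm, "feature_matrix"))
  g <- fm$geometry
  m <- matrix(NA_real_, g$dim[1L], g$dim[2L])
  m[cbind(fm$loc$row, fm$loc$col)] <- cm$location_labels
  grid_field(m, g$origin_x, g$origin_y, g$cell_size,
             nodata = !is.finite(m), attribute = "cluster", units = "id")
}

#' Map of clusters and sampling sites
#'
#' @param cm a [cluster_field()] result.
#' @param fm the matching `feature_matrix`.
#' @param design optional `sampling_design` whose sites are overplotted.
#' @param ... passed to [graphics::plot()].
#' @export
plot_cluster_map <- function(cm, fm, design = NULL, ...) {
  pal <- grDevices::hcl.colors(cm$k, "Dark 3")
  graphics::plot(fm$loc$x, fm$loc$y, col = pal[cm$location_labels],
                 pch = 15, cex = 0.5, asp = 1, xlab = "easting (m)",
                 ylab = "northing (m)", main = "Field clusters", ...)
  if (!is.null(design)) {
    s <- design$sites
    graphics::points(s$x, s$y, pch = ifelse(s$role == "BMU", 8, 21),
                     bg = "white", cex = 1.2)
  }
  invisible(NULL)
}
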