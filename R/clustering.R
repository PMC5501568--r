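#' K-means with seeded restarts and empty-cluster repair
#'
#' Runs Lloyd's iteration (via [stats::kmeans()]) from `n_restarts`
#' seeded draws of `k` distinct rows as initial centers and keeps the
#' fit with the lowest within-cluster sum of squares.  A restart that
#' produces an empty cluster is repaired by re-seeding the empty center
#' at the point farthest from its assigned center and rerunning.
#'
#' @param vectors numeric matrix, one row per object.
#' @param k number of clusters; must not exceed the number of distinct
#'   rows.
#' @param n_restarts number of seeded restarts (default 10).
#' @param seed RNG seed; the fit is deterministic given it.
#' @return list with `labels` (1..k per row), `centers` (k x ncol),
#'   `sse` (total within-cluster sum of squares) and `size`.
#' @export
kmeans_fit <- function(vectors, k, n_restarts = 10, seed = 1L) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  ndistinct <- nrow(unique(vectors))
  if (k > ndistinct)
    stop("k = ", k, " exceeds the ", ndistinct, " distinct vectors",
         call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  distinct_start <- function() {
    # sample k distinct rows as initial centers
    for (try in 1:100) {
      ctr <- vectors[sample.int(n, k), , drop = FALSE]
      if (nrow(unique(ctr)) == k) return(ctr)
    }
    unique(vectors)[sample.int(ndistinct, k), , drop = FALSE]
  }

  run_once <- function(centers) {
    for (repair in 0:20) {
      fit <- tryCatch(
        suppressWarnings(kmeans(vectors, centers, iter.max = 200,
                                algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit) || any(fit$size == 0L)) {
        # re-seed failed/empty centers at the farthest point
        if (is.null(fit)) {
          centers <- distinct_start()
          next
        }
        lab <- fit$cluster
        d2 <- rowSums((vectors - fit$centers[lab, , drop = FALSE])^2)
        far <- order(d2, decreasing = TRUE)
        empties <- which(fit$size == 0L)
        centers <- fit$centers
        centers[empties, ] <- vectors[far[seq_along(empties)], , drop = FALSE]
        next
      }
      return(fit)
    }
    stop("K-means failed to produce ", k, " non-empty clusters",
         call. = FALSE)
  }

  best <- NULL
  for (r in seq_len(max(1L, as.integer(n_restarts)))) {
    fit <- run_once(distinct_start())
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  list(labels = unname(best$cluster), centers = unname(best$centers),
       sse = best$tot.withinss, size = unname(best$size))
}

#' Cluster the field through the trained map
#'
#' K-means partitions the codebook's node vectors; every field location
#' then inherits the cluster of its winning node.  Cluster ids are
#' renumbered by descending location membership (cluster 1 largest) for
#' stable reporting, and input-space centroids are recomputed from the
#' member locations.
#'
#' @param cb a trained [som_codebook()].
#' @param fm the normalized `feature_matrix`.
#' @param k number of clusters (>= 2); typically chosen by inspecting
#'   the [compute_umatrix()] ridges, see also [davies_bouldin_scan()].
#' @param n_restarts,seed passed to [kmeans_fit()].
#' @return An object of class `cluster_model`: `k`, `node_labels`,
#'   `location_labels`, `centroids` (k x k-attrs, normalized units,
#'   means of member locations), `centroids_raw` (same in raw units when
#'   normalization is available), `size` (locations per cluster),
#'   `sse` (within-cluster sum of squares over locations),
#'   `node_sse` (K-means objective over node vectors).
#' @export
cluster_field <- function(cb, fm, k, n_restarts = 10, seed = 1L) {
  stopifnot(inherits(cb, "som_codebook"), inherits(fm, "feature_matrix"))
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  km <- kmeans_fit(cb$codes, k, n_restarts = n_restarts, seed = seed)
  win <- map_winners(fm, cb)
  loc_lab <- km$labels[win$index]
  counts <- tabulate(loc_lab, nbins = k)
  if (any(counts == 0L))
    stop("cluster with zero member locations; try a smaller k",
         call. = FALSE)
  # renumber by descending membership
  ord <- order(counts, decreasing = TRUE)
  remap <- integer(k); remap[ord] <- seq_len(k)
  node_lab <- remap[km$labels]
  loc_lab <- remap[loc_lab]
  centroids <- t(vapply(seq_len(k), function(cl)
    colMeans(fm$X[loc_lab == cl, , drop = FALSE]), numeric(ncol(fm$X))))
  colnames(centroids) <- colnames(fm$X)
  centroids_raw <- if (is_normalized(fm))
    sweep(sweep(centroids, 2L, fm$normalization$scale, `*`),
          2L, fm$normalization$center, `+`)
  sse <- sum(rowSums((fm$X - centroids[loc_lab, , drop = FALSE])^2))
  structure(
    list(k = k, node_labels = node_lab, location_labels = loc_lab,
         centroids = centroids, centroids_raw = centroids_raw,
         size = tabulate(loc_lab, nbins = k), sse = sse,
         node_sse = km$sse, seed = seed),
    class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d; locations per cluster: %s\n",
              x$k, paste(x$size, collapse = ", ")))
  cat(sprintf("  within-cluster SSE (locations): %.4g\n", x$sse))
  invisible(x)
}

#' Davies-Bouldin index scan over candidate cluster counts
#'
#' Guidance only: the cluster count is ultimately a user decision made
#' by inspecting the U-matrix.  Lower index = better separated, more
#' compact clusters.
#'
#' @param cb a trained [som_codebook()].
#' @param k_range candidate cluster counts.
#' @param n_restarts,seed passed to [kmeans_fit()].
#' @return data frame with `k` and `davies_bouldin`.
#' @export
davies_bouldin_scan <- function(cb, k_range = 2:8, n_restarts = 10,
                                seed = 1L) {
  stopifnot(inherits(cb, "som_codebook"))
  X <- cb$codes
  db <- vapply(k_range, function(k) {
    km <- kmeans_fit(X, k, n_restarts = n_restarts, seed = seed)
    s <- vapply(seq_len(k), function(cl) {
      m <- X[km$labels == cl, , drop = FALSE]
      mean(sqrt(rowSums((m - matrix(km$centers[cl, ], nrow(m), ncol(m),
                                    byrow = TRUE))^2)))
    }, numeric(1))
    dc <- as.matrix(stats::dist(km$centers))
    mean(vapply(seq_len(k), function(i)
      max(((s[i] + s[-i]) / dc[i, -i])), numeric(1)))
  }, numeric(1))
  data.frame(k = k_range, davies_bouldin = db)
}
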