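#' Unified distance matrix (U-matrix)
#'
#' For every pair of lattice-adjacent nodes, the Euclidean distance
#' between their prototype vectors; per-node values are the mean of the
#' incident edge distances.  Ridges of high distance mark cluster
#' boundaries on the map.  Hexagonal lattices use 6-neighbourhoods
#' (interior nodes), rectangular lattices 4-neighbourhoods; edge nodes
#' have fewer neighbours.
#'
#' @param cb a [som_codebook()].
#' @return An object of class `umatrix`: `edges` (data frame `i`, `j`,
#'   `distance`, node indices with `i < j`), `node_value` (mean incident
#'   distance per node), and the lattice layout for plotting.
#' @export
compute_umatrix <- function(cb) {
  stopifnot(inherits(cb, "som_codebook"))
  lat <- cb$lattice
  N <- nrow(lat)
  # adjacency: unit lattice distance (both topologies place neighbours
  # at distance exactly 1)
  pr <- which(outer(lat[, 1], lat[, 1], `-`)^2 +
                outer(lat[, 2], lat[, 2], `-`)^2 < 1.01^2, arr.ind = TRUE)
  pr <- pr[pr[, 1] < pr[, 2], , drop = FALSE]
  dvec <- sqrt(rowSums((cb$codes[pr[, 1], , drop = FALSE] -
                          cb$codes[pr[, 2], , drop = FALSE])^2))
  node_value <- vapply(seq_len(N), function(i) {
    inc <- dvec[pr[, 1] == i | pr[, 2] == i]
    if (length(inc)) mean(inc) else 0
  }, numeric(1))
  structure(
    list(edges = data.frame(i = pr[, 1], j = pr[, 2], distance = dvec),
         node_value = node_value, lattice = lat,
         rows = cb$rows, cols = cb$cols, topology = cb$topology),
    class = "umatrix")
}

#' @export
print.umatrix <- function(x, ...) {
  cat(sprintf("<umatrix> %d nodes, %d edges; edge distance %.3g .. %.3g\n",
              length(x$node_value), nrow(x$edges),
              min(x$edges$distance), max(x$edges$distance)))
  invisible(x)
}

#' Heatmap of U-matrix node values
#'
#' @param x a [compute_umatrix()] result.
#' @param ... passed to [graphics::points()].
#' @export
plot.umatrix <- function(x, ...) {
  pal <- grDevices::hcl.colors(64, "viridis")
  v <- x$node_value
  col <- pal[pmax(1L, ceiling(64 * (v - min(v)) /
                                max(max(v) - min(v), .Machine$double.eps)))]
  graphics::plot(x$lattice[, 1], x$lattice[, 2], pch = 21, bg = col,
                 cex = 2, asp = 1, xlab = "lattice x", ylab = "lattice y",
                 main = "U-matrix (mean neighbour distance)", ...)
  invisible(x)
}

#' Save / load a codebook bundle
#'
#' Serializes lattice dimensions, topology, node vectors, normalization
#' parameters, training schedule and seeds to a versioned JSON file so
#' clustering and site selection can be re-run without retraining.
#'
#' @param cb a [som_codebook()].
#' @param fm the `feature_matrix` whose normalization should travel with
#'   the codebook (optional).
#' @param path output path (`.json`).
#' @return `path` invisibly; `read_codebook()` returns a list with the
#'   restored `codebook` and the `normalization` parameters.
#' @export
write_codebook <- function(cb, path, fm = NULL) {
  stopifnot(inherits(cb, "som_codebook"))
  bundle <- list(
    format = "somzones-codebook", version = 1L,
    rows = cb$rows, cols = cb$cols, topology = cb$topology, k = cb$k,
    init = cb$init, seed = cb$seed, trained = cb$trained,
    train_seed = cb$train_seed,
    schedule = cb$schedule,
    colnames = colnames(cb$codes),
    codes = unname(as.data.frame(cb$codes)),
    normalization = if (!is.null(fm) && is_normalized(fm))
      fm$normalization)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(b$format, "somzones-codebook"))
    stop("not a somzones codebook bundle: ", path, call. = FALSE)
  codes <- as.matrix(b$codes)
  dimnames(codes) <- list(NULL, b$colnames)
  cb <- structure(
    list(codes = codes, rows = b$rows, cols = b$cols,
         topology = b$topology,
         lattice = lattice_coords(b$rows, b$cols, b$topology),
         k = b$k, init = b$init, seed = b$seed,
         trained = isTRUE(b$trained),
         train_seed = b$train_seed,
         schedule = if (!is.null(b$schedule)) as.data.frame(b$schedule)),
    class = "som_codebook")
  list(codebook = cb, normalization = b$normalization)
}
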