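#' Assemble the location-by-attribute feature matrix
#'
#' Stacks co-registered grid layers into one row per field location and
#' one column per attribute, keeping only cells that carry data in every
#' layer.  The canonical layer order for zone delineation is elevation,
#' slope, aspect, plan curvature, H-H EMI, V-V EMI (k = 6), but any list
#' of layers is accepted.
#'
#' @param layers named list of [grid_field()] objects on identical
#'   geometry; names become column names (falling back to each layer's
#'   `attribute` label).
#' @return An object of class `feature_matrix`: list with `X` (n x k
#'   numeric matrix), `loc` (data frame of grid `row`, `col` and map
#'   `x`, `y` per record), `normalization` (`"raw"` here), and the grid
#'   geometry for writing label rasters.
#' @export
build_feature_matrix <- function(layers) {
  if (!is.list(layers) || length(layers) < 1L)
    stop("layers must be a non-empty list of grid_field objects",
         call. = FALSE)
  ref <- layers[[1L]]
  for (l in layers) {
    stopifnot(inherits(l, "grid_field"))
    if (!same_geometry(ref, l))
      stop("all layers must share grid geometry", call. = FALSE)
  }
  nms <- names(layers)
  if (is.null(nms)) nms <- rep("", length(layers))
  auto <- vapply(layers, function(l) l$attribute, character(1))
  nms <- ifelse(nzchar(nms), nms, auto)
  valid <- Reduce(`&`, lapply(layers, function(l) !l$nodata))
  idx <- which(valid)                    # column-major over the grid
  if (length(idx) < 1L)
    stop("no cell is valid in every layer", call. = FALSE)
  X <- vapply(layers, function(l) l$values[idx], numeric(length(idx)))
  X <- matrix(X, nrow = length(idx), dimnames = list(NULL, nms))
  cc <- grid_coords(ref)
  rc <- arrayInd(idx, dim(ref$values))
  loc <- data.frame(row = rc[, 1L], col = rc[, 2L],
                    x = cc$x[rc[, 2L]], y = cc$y[rc[, 1L]])
  structure(
    list(X = X, loc = loc, normalization = "raw",
         geometry = list(dim = dim(ref$values), origin_x = ref$origin_x,
                         origin_y = ref$origin_y, cell_size = ref$cell_size)),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  norm <- if (identical(x$normalization, "raw")) "raw"
          else "normalized (z-score)"
  cat(sprintf("<feature_matrix> %d locations x %d attributes, %s\n",
              nrow(x$X), ncol(x$X), norm))
  cat("  attributes:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$X)

#' Z-score normalization of a feature matrix
#'
#' Centers and scales every column to mean 0, standard deviation 1, and
#' stores the column means and SDs so cluster profiles and distances can
#' be reported back in raw attribute units.
#'
#' @param fm a raw [build_feature_matrix()] result.
#' @return The normalized `feature_matrix`; `normalization` holds
#'   `center` and `scale` vectors.
#' @export
normalize_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!identical(fm$normalization, "raw"))
    stop("feature matrix is already normalized", call. = FALSE)
  ctr <- colMeans(fm$X)
  scl <- apply(fm$X, 2L, sd)
  bad <- which(scl == 0 | !is.finite(scl))
  if (length(bad))
    stop("cannot normalize constant column(s): ",
         paste(colnames(fm$X)[bad], collapse = ", "), call. = FALSE)
  fm$X <- scale(fm$X, center = ctr, scale = scl)
  attr(fm$X, "scaled:center") <- NULL
  attr(fm$X, "scaled:scale") <- NULL
  fm$normalization <- list(center = ctr, scale = scl)
  fm
}

#' Undo feature normalization
#'
#' @param fm a normalized `feature_matrix`.
#' @return The `feature_matrix` in raw units.
#' @export
denormalize_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (identical(fm$normalization, "raw")) return(fm)
  fm$X <- sweep(sweep(fm$X, 2L, fm$normalization$scale, `*`),
                2L, fm$normalization$center, `+`)
  fm$normalization <- "raw"
  fm
}

is_normalized <- function(fm) !identical(fm$normalization, "raw")

#' Export a feature matrix to CSV
#'
#' Writes one row per location with grid indices, coordinates, raw
#' values and (if normalized) z-scores.
#'
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- cbind(fm$loc, as.data.frame(unclass(fm$X)))
  if (is_normalized(fm)) {
    raw <- denormalize_features(fm)
    names(out)[-(1:4)] <- paste0(colnames(fm$X), "_z")
    out <- cbind(out, as.data.frame(unclass(raw$X)))
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
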