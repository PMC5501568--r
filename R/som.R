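#' Self-organizing map codebook
#'
#' Creates the lattice of prototype ("node") vectors that the SOM trains.
#' Node `i` (1-based, row-major over the lattice) has fixed lattice
#' coordinates; on a hexagonal lattice odd rows are offset half a unit
#' and rows are `sqrt(3)/2` apart so the six neighbours of an interior
#' node are all at unit distance.
#'
#' The default map size follows the common SOM-toolbox heuristic:
#' `N = ceil(5 * sqrt(n))` nodes, with the row:column ratio matched to
#' the square root of the ratio of the two leading eigenvalues of the
#' data covariance.  The default "linear" initialization lays the node
#' vectors on the plane spanned by the first two principal components,
#' spanning plus/minus 2 SD along each — deterministic given the data.
#' `init = "random"` instead samples input rows with the given seed.
#'
#' @param fm a normalized [feature_matrix][build_feature_matrix()].
#' @param rows,cols lattice dimensions; both `NULL` for the heuristic.
#' @param topology `"hexagonal"` (default) or `"rectangular"`.
#' @param init `"linear"` (default) or `"random"`.
#' @param seed RNG seed used by random initialization.
#' @return An object of class `som_codebook`: `codes` (N x k matrix),
#'   `rows`, `cols`, `topology`, `lattice` (N x 2 coordinates), `seed`.
#' @export
som_codebook <- function(fm, rows = NULL, cols = NULL,
                         topology = c("hexagonal", "rectangular"),
                         init = c("linear", "random"), seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!is_normalized(fm))
    stop("the codebook is initialized from normalized features; ",
         "call normalize_features() first", call. = FALSE)
  topology <- match.arg(topology)
  init <- match.arg(init)
  X <- fm$X
  n <- nrow(X); k <- ncol(X)

  if (is.null(rows) || is.null(cols)) {
    munits <- ceiling(5 * sqrt(n))
    ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
    ratio <- if (length(ev) >= 2L && ev[2] > 0) sqrt(ev[1] / ev[2]) else 1
    rows <- max(2L, round(sqrt(munits * ratio)))
    cols <- max(2L, round(munits / rows))
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 2L) stop("lattice needs at least 2 nodes", call. = FALSE)

  lat <- lattice_coords(rows, cols, topology)
  N <- rows * cols

  if (init == "linear" && k < 2L) {
    warning("linear initialization needs k >= 2; falling back to random init")
    init <- "random"
  }
  if (init == "linear") {
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    mu <- colMeans(X)
    sd1 <- pc$sdev[1]; sd2 <- pc$sdev[2]
    # map PC1 along the longer lattice axis
    g <- expand.grid(r = seq_len(rows), c = seq_len(cols))
    a_long <- if (cols >= rows) scaled_axis(g$c, cols) else scaled_axis(g$r, rows)
    a_short <- if (cols >= rows) scaled_axis(g$r, rows) else scaled_axis(g$c, cols)
    # expand.grid varies r fastest; reorder to row-major (c fastest)
    ord <- order(g$r, g$c)
    codes <- matrix(mu, N, k, byrow = TRUE) +
      outer(a_long[ord], 2 * sd1 * pc$rotation[, 1]) +
      outer(a_short[ord], 2 * sd2 * pc$rotation[, 2])
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    codes <- X[sample.int(n, N, replace = N > n), , drop = FALSE]
  }
  dimnames(codes) <- list(NULL, colnames(X))
  structure(
    list(codes = codes, rows = rows, cols = cols, topology = topology,
         lattice = lat, k = k, init = init, seed = seed, trained = FALSE),
    class = "som_codebook")
}

scaled_axis <- function(i, len) if (len == 1L) rep(0, length(i)) else
  (i - 1) / (len - 1) * 2 - 1

lattice_coords <- function(rows, cols, topology) {
  g <- expand.grid(c = seq_len(cols), r = seq_len(rows))  # row-major order
  if (topology == "hexagonal") {
    cbind(x = g$c - 1 + 0.5 * ((g$r - 1) %% 2), y = (g$r - 1) * sqrt(3) / 2)
  } else {
    cbind(x = g$c - 1, y = g$r - 1)
  }
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' @export
print.som_codebook <- function(x, ...) {
  cat(sprintf("<som_codebook> %d x %d %s lattice (%d nodes), k = %d, %s\n",
              x$rows, x$cols, x$topology, nrow(x$codes), x$k,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Winning node for an input vector
#'
#' The winner is the node whose prototype has the smallest Euclidean
#' distance to the input; ties go to the lowest node index.
#'
#' @param x numeric vector of length k.
#' @param cb a [som_codebook()].
#' @return list with `index` (1-based node index) and `distance`.
#' @export
find_bmu_node <- function(x, cb) {
  stopifnot(inherits(cb, "som_codebook"))
  if (length(x) != cb$k)
    stop("input vector has length ", length(x), ", codebook expects ", cb$k,
         call. = FALSE)
  r <- bmu_cpp(matrix(as.numeric(x), 1L), cb$codes)
  list(index = r$index[1L] + 1L, distance = r$distance[1L])
}

#' Winning nodes for every row of a feature matrix
#'
#' @param fm a `feature_matrix` (normalized, matching the codebook).
#' @param cb a [som_codebook()].
#' @return list with integer vector `index` and numeric `distance`.
#' @export
map_winners <- function(fm, cb) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cb, "som_codebook"))
  if (ncol(fm$X) != cb$k) stop("dimension mismatch", call. = FALSE)
  r <- bmu_cpp(fm$X, cb$codes)
  list(index = r$index + 1L, distance = r$distance)
}

#' Default two-phase training schedule
#'
#' Rough phase: neighborhood radius from `max(rows, cols)/4` down to 1
#' lattice unit, learning rate 0.5 to 0.05, over `10 n` steps.  Fine
#' phase: radius 1 to 0.1, rate 0.05 to 0.01, over `40 n` steps.  Both
#' decay linearly within the phase; the neighborhood is Gaussian,
#' `h = alpha * exp(-d^2 / (2 sigma^2))`.
#'
#' @param n number of input rows.
#' @param rows,cols lattice dimensions.
#' @param scale multiplier on both phase lengths (use < 1 for quick
#'   exploratory fits).
#' @return data frame with columns `t_max`, `alpha0`, `alpha1`,
#'   `sigma0`, `sigma1`, one row per phase.
#' @export
som_schedule <- function(n, rows, cols, scale = 1) {
  sched <- data.frame(
    t_max = ceiling(c(10, 40) * n * scale),
    alpha0 = c(0.5, 0.05), alpha1 = c(0.05, 0.01),
    sigma0 = c(max(max(rows, cols) / 4, 1), 1), sigma1 = c(1, 0.1))
  validate_schedule(sched)
  sched
}

validate_schedule <- function(s) {
  stopifnot(is.data.frame(s),
            all(c("t_max", "alpha0", "alpha1", "sigma0", "sigma1") %in%
                  names(s)))
  with(s, {
    if (any(t_max < 1) || any(alpha0 <= 0) || any(alpha1 <= 0) ||
        any(sigma0 <= 0) || any(sigma1 <= 0))
      stop("schedule rates, radii and lengths must be positive",
           call. = FALSE)
    if (any(alpha1 > alpha0) || any(sigma1 > sigma0))
      stop("rates and radii must be non-increasing within a phase",
           call. = FALSE)
  })
  invisible(s)
}

#' Train a self-organizing map
#'
#' Sequential Kohonen training: at each step a random input row is
#' presented, its winner found, and every node moved toward the input by
#' the Gaussian neighborhood weight
#' `h_ci = alpha(t) * exp(-d_lattice(c, i)^2 / (2 sigma(t)^2))`.
#'
#' @param cb a [som_codebook()].
#' @param fm the normalized `feature_matrix` the codebook was built from.
#' @param schedule a schedule from [som_schedule()]; `NULL` for the
#'   default.
#' @param seed RNG seed driving input sampling.
#' @return The trained `som_codebook`.
#' @export
som_train <- function(cb, fm, schedule = NULL, seed = 1L) {
  stopifnot(inherits(cb, "som_codebook"), inherits(fm, "feature_matrix"))
  if (!is_normalized(fm))
    stop("training expects normalized features", call. = FALSE)
  if (ncol(fm$X) != cb$k) stop("dimension mismatch", call. = FALSE)
  if (is.null(schedule)) schedule <- som_schedule(nrow(fm$X), cb$rows, cb$cols)
  validate_schedule(schedule)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  ph <- as.matrix(schedule[, c("t_max", "alpha0", "alpha1",
                               "sigma0", "sigma1")])
  cb$codes <- som_train_cpp(fm$X, cb$codes, cb$lattice, ph)
  dimnames(cb$codes) <- list(NULL, colnames(fm$X))
  cb$trained <- TRUE
  cb$schedule <- schedule
  cb$train_seed <- seed
  cb
}

#' Quantization error of a map
#'
#' Mean Euclidean distance from each input row to its winning node; the
#' standard SOM fit metric (smaller is better).
#'
#' @inheritParams som_train
#' @return A non-negative number.
#' @export
quantization_error <- function(cb, fm) {
  stopifnot(inherits(cb, "som_codebook"), inherits(fm, "feature_matrix"))
  if (nrow(fm$X) < 1L) stop("empty feature matrix", call. = FALSE)
  mean(map_winners(fm, cb)$distance)
}
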