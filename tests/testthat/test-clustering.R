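test_that("kmeans_fit handles degenerate k and finds the global optimum", {
  set.seed(20)
  X <- matrix(rnorm(16), 8, 2)
  # k = n distinct vectors: SSE 0
  fit <- kmeans_fit(X, 8, seed = 1)
  expect_equal(fit$sse, 0, tolerance = 1e-12)
  expect_equal(sort(unique(fit$labels)), 1:8)
  # k = 1: centroid is the mean
  fit1 <- kmeans_fit(X, 1, seed = 1)
  expect_equal(as.vector(fit1$centers), colMeans(X), tolerance = 1e-12)
  # k = 2 on 8 points: matches exhaustive enumeration of all 2-partitions
  sse_part <- function(idx) {
    a <- X[idx, , drop = FALSE]; b <- X[-idx, , drop = FALSE]
    sum(scale(a, scale = FALSE)^2) + sum(scale(b, scale = FALSE)^2)
  }
  best <- Inf
  for (sz in 1:4) for (cmb in asplit(utils::combn(8, sz), 2))
    best <- min(best, sse_part(cmb))
  fit2 <- kmeans_fit(X, 2, n_restarts = 20, seed = 3)
  expect_equal(fit2$sse, best, tolerance = 1e-9)
  expect_error(kmeans_fit(X, 9), "distinct")
})

test_that("kmeans_fit is deterministic and repairs duplicate-heavy input", {
  X <- rbind(matrix(0, 5, 2), matrix(1, 5, 2), c(0, 1), c(1, 0))
  f1 <- kmeans_fit(X, 4, seed = 6)
  f2 <- kmeans_fit(X, 4, seed = 6)
  expect_identical(f1$labels, f2$labels)
  expect_true(all(f1$size > 0))
})

test_that("field clustering propagates labels through the winner nodes", {
  set.seed(21)
  # two point masses: codebook trained on them separates locations exactly
  X <- rbind(matrix(rnorm(300, -3, 0.2), 150, 2),
             matrix(rnorm(300, 3, 0.2), 150, 2))
  fm <- as_fm(X)
  cb <- som_train(som_codebook(fm, rows = 2, cols = 4), fm, seed = 2)
  cm <- cluster_field(cb, fm, k = 2, seed = 2)
  truth <- rep(1:2, each = 150)
  expect_gte(score_zone_recovery(cm$location_labels, truth)$accuracy, 1)
  # location label equals its winner node's label
  win <- map_winners(fm, cb)
  expect_equal(cm$location_labels, cm$node_labels[win$index])
  # determinism
  cm2 <- cluster_field(cb, fm, k = 2, seed = 2)
  expect_identical(cm$location_labels, cm2$location_labels)
  # clusters ordered by descending membership
  expect_true(all(diff(cm$size) <= 0))
  # centroids are member means
  for (cl in 1:2)
    expect_equal(cm$centroids[cl, ],
                 colMeans(fm$X[cm$location_labels == cl, , drop = FALSE]),
                 tolerance = 1e-9)
})

test_that("BMU location is the member closest to its centroid", {
  set.seed(22)
  fm <- as_fm(matrix(rnorm(200), 100, 2))
  cb <- som_train(som_codebook(fm, rows = 2, cols = 3), fm, seed = 1)
  cm <- cluster_field(cb, fm, k = 3, seed = 1)
  des <- select_bmu_location(cm, fm)
  for (cl in 1:3) {
    members <- which(cm$location_labels == cl)
    d2 <- rowSums((fm$X[members, , drop = FALSE] -
                     matrix(cm$centroids[cl, ], length(members), 2,
                            byrow = TRUE))^2)
    expect_equal(des$sites$row[cl], members[which.min(d2)])
    expect_equal(des$sites$dist_to_centroid[cl], sqrt(min(d2)),
                 tolerance = 1e-9)
  }
  # a member exactly at the centroid is selected with distance 0
  X <- rbind(c(0, 0), c(2, 0), c(-2, 0), c(0, 2), c(0, -2), c(9, 9), c(11, 11))
  fmx <- as_fm(X)
  cmx <- list(k = 2, location_labels = c(1, 1, 1, 1, 1, 2, 2),
              centroids = rbind(c(0, 0), c(10, 10)), size = c(5, 2))
  class(cmx) <- "cluster_model"
  dx <- select_bmu_location(cmx, fmx)
  expect_equal(dx$sites$row[1], 1L)
  expect_equal(dx$sites$dist_to_centroid[1], 0)
  # tie between equidistant members -> lowest row index
  expect_equal(dx$sites$row[2], 6L)
})

test_that("additional sites spread greedily and count k*(1+n)", {
  set.seed(23)
  fm <- as_fm(matrix(rnorm(400), 200, 2))
  cb <- som_train(som_codebook(fm, rows = 2, cols = 4), fm, seed = 3)
  cm <- cluster_field(cb, fm, k = 3, seed = 3)
  des <- select_additional_sites(cm, fm, n_per_cluster = 11)
  expect_equal(des$sites_total, 36L)
  expect_equal(nrow(des$sites), 36L)
  expect_false(any(duplicated(des$sites$row)))
  expect_equal(as.vector(table(des$sites$cluster)), rep(12L, 3))
  # matches the independent naive greedy oracle per cluster
  bmu <- select_bmu_location(cm, fm)
  for (cl in 1:3) {
    members <- which(cm$location_labels == cl)
    start <- match(bmu$sites$row[cl], members)
    oracle <- members[greedy_oracle(fm$loc$x[members], fm$loc$y[members],
                                    start, 12)]
    expect_equal(des$sites$row[des$sites$cluster == cl], oracle)
  }
})

test_that("small clusters are exhausted with a reported shortfall", {
  X <- rbind(matrix(rnorm(10), 5, 2), matrix(rnorm(180, 8), 90, 2))
  fmx <- as_fm(X)
  cmx <- list(k = 2, location_labels = c(rep(2, 5), rep(1, 90)),
              centroids = rbind(colMeans(X[6:95, ]), colMeans(X[1:5, ])),
              size = c(90, 5))
  class(cmx) <- "cluster_model"
  expect_message(des <- select_additional_sites(cmx, fmx, 11), "shortfall")
  expect_equal(sum(des$sites$cluster == 2), 5L)
  expect_equal(des$sites_total, 17L)
  # cluster with exactly 1 + n members: all selected, no shortfall
  des2 <- select_additional_sites(cmx, fmx, 4)
  expect_equal(sum(des2$sites$cluster == 2), 5L)
  expect_length(des2$shortfall, 0)
})

test_that("greedy dispersion attains at least half the exhaustive optimum", {
  set.seed(24)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    x <- runif(n, 0, 100); y <- runif(n, 0, 100)
    sel <- somzones:::farthest_point_selection(x, y, start = 1, n_total = 3)
    minpair <- function(s) min(dist(cbind(x[s], y[s])))
    best <- max(apply(utils::combn(2:n, 2), 2,
                      function(cc) minpair(c(1, cc))))
    expect_gte(minpair(sel), best / 2 - 1e-9)
  }
})
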