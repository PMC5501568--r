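test_that("codebook initialization is deterministic and handles degeneracy", {
  set.seed(5)
  fm <- as_fm(matrix(rnorm(200 * 3), 200))
  cb1 <- som_codebook(fm, rows = 4, cols = 5)
  cb2 <- som_codebook(fm, rows = 4, cols = 5)
  expect_identical(cb1$codes, cb2$codes)          # linear init: no RNG
  # all rows identical -> every node vector equals that row
  v <- c(1.5, -2, 0.5)
  fme <- as_fm(matrix(v, 50, 3, byrow = TRUE))
  cbe <- som_codebook(fme, rows = 3, cols = 3)
  expect_equal(cbe$codes, matrix(v, 9, 3, byrow = TRUE,
                                 dimnames = dimnames(cbe$codes)),
               tolerance = 1e-12)
  # random init reproducible under seed
  cr1 <- som_codebook(fm, rows = 4, cols = 5, init = "random", seed = 42)
  cr2 <- som_codebook(fm, rows = 4, cols = 5, init = "random", seed = 42)
  expect_identical(cr1$codes, cr2$codes)
  # k = 1 falls back to random init with a warning
  expect_warning(som_codebook(as_fm(matrix(rnorm(50))), rows = 2, cols = 2),
                 "random")
})

test_that("winner lookup matches exhaustive search and breaks ties low", {
  set.seed(8)
  cb <- as_codebook(matrix(rnorm(12 * 4), 12), rows = 3, cols = 4)
  # exact node match
  hit <- find_bmu_node(cb$codes[3, ], cb)
  expect_equal(hit$index, 3L)
  expect_equal(hit$distance, 0)
  # nearer of two nodes
  cb2 <- as_codebook(rbind(c(0, 0), c(1, 1)), rows = 1, cols = 2)
  expect_equal(find_bmu_node(c(0.9, 0.9), cb2)$index, 2L)
  # tie -> lowest index
  cb3 <- as_codebook(rbind(c(0, 1), c(0, -1), c(0, 1)), rows = 1, cols = 3)
  expect_equal(find_bmu_node(c(1, 0), cb3)$index, 1L)
  # random queries vs R argmin oracle
  for (rep in 1:25) {
    x <- rnorm(4)
    d <- sqrt(colSums((t(cb$codes) - x)^2))
    expect_equal(find_bmu_node(x, cb)$index, which.min(d))
    expect_equal(find_bmu_node(x, cb)$distance, min(d), tolerance = 1e-12)
  }
  expect_error(find_bmu_node(c(1, 2), cb), "length")
})

test_that("one training step with h = 1 moves the winner onto the input", {
  cb <- as_codebook(rbind(c(0, 0), c(5, 5), c(9, -3)), rows = 1, cols = 3)
  x <- c(4.2, 4.9)                       # winner is node 2
  fm <- as_fm(matrix(x, 1))
  sched <- data.frame(t_max = 1, alpha0 = 1, alpha1 = 1,
                      sigma0 = 1e-6, sigma1 = 1e-6)
  out <- som_train(cb, fm, sched, seed = 1)
  expect_equal(unname(out$codes[2, ]), x, tolerance = 1e-12)
  expect_equal(unname(out$codes[1, ]), c(0, 0))  # outside the neighborhood
  expect_equal(unname(out$codes[3, ]), c(9, -3))
})

test_that("training contracts the map onto a single repeated input", {
  v <- c(2, -1, 0.5)
  fm <- as_fm(matrix(v, 40, 3, byrow = TRUE))
  set.seed(9)
  cb <- som_codebook(fm, rows = 3, cols = 3, init = "random", seed = 3)
  cb$codes <- cb$codes + rnorm(27)       # perturb away from v
  out <- som_train(cb, fm, seed = 2)
  expect_true(all(abs(sweep(out$codes, 2, v)) < 1e-3))
})

test_that("training reduces quantization error and is bit-reproducible", {
  set.seed(10)
  X <- rbind(matrix(rnorm(120, -2), 60, 2), matrix(rnorm(120, 2), 60, 2))
  fm <- as_fm(X)
  cb0 <- som_codebook(fm, rows = 4, cols = 4)
  tr1 <- som_train(cb0, fm, seed = 7)
  tr2 <- som_train(cb0, fm, seed = 7)
  expect_identical(tr1$codes, tr2$codes)
  expect_lte(quantization_error(tr1, fm), quantization_error(cb0, fm))
})

test_that("trained node coordinates stay inside the data/init hull", {
  set.seed(12)
  fm <- as_fm(matrix(rnorm(300), 100, 3))
  cb <- som_codebook(fm, rows = 3, cols = 4)
  tr <- som_train(cb, fm, seed = 5)
  lo <- pmin(apply(fm$X, 2, min), apply(cb$codes, 2, min))
  hi <- pmax(apply(fm$X, 2, max), apply(cb$codes, 2, max))
  expect_true(all(sweep(tr$codes, 2, lo, `>=`)))
  expect_true(all(sweep(tr$codes, 2, hi, `<=`)))
})

test_that("quantization error matches direct computation and monotonicity", {
  set.seed(13)
  X <- matrix(rnorm(60), 20, 3)
  fm <- as_fm(X)
  # single node: mean distance to it
  m <- rnorm(3)
  cb1 <- as_codebook(rbind(m, m), rows = 1, cols = 2)  # duplicated node
  expect_equal(quantization_error(cb1, fm),
               mean(sqrt(colSums((t(X) - m)^2))), tolerance = 1e-12)
  # inputs equal to node vectors -> 0
  cbx <- as_codebook(X[1:4, ], rows = 2, cols = 2)
  expect_equal(quantization_error(cbx, as_fm(X[1:4, ])), 0)
  # adding a node never increases QE
  for (rep in 1:10) {
    base <- matrix(rnorm(12), 4, 3)
    qe1 <- quantization_error(as_codebook(base, 2, 2), fm)
    qe2 <- quantization_error(as_codebook(rbind(base, rnorm(3)), 1, 5), fm)
    expect_lte(qe2, qe1 + 1e-12)
  }
})

test_that("U-matrix edges equal neighbour prototype distances", {
  # identical nodes -> all zero
  cbz <- as_codebook(matrix(1, 6, 2), rows = 2, cols = 3)
  um <- compute_umatrix(cbz)
  expect_true(all(um$edges$distance == 0))
  expect_true(all(um$node_value == 0))
  # 1 x 2 map: the single edge is the prototype distance
  cb2 <- as_codebook(rbind(c(0, 0), c(3, 4)), rows = 1, cols = 2)
  um2 <- compute_umatrix(cb2)
  expect_equal(nrow(um2$edges), 1L)
  expect_equal(um2$edges$distance, 5)
  # random hexagonal codebook vs pairwise-distance oracle
  set.seed(14)
  cb3 <- as_codebook(matrix(rnorm(20 * 3), 20), 4, 5,
                     topology = "hexagonal")
  um3 <- compute_umatrix(cb3)
  D <- as.matrix(dist(cb3$codes))
  for (e in seq_len(nrow(um3$edges)))
    expect_equal(um3$edges$distance[e],
                 D[um3$edges$i[e], um3$edges$j[e]], tolerance = 1e-12)
  # interior hexagonal node has 6 incident edges
  inc <- tabulate(c(um3$edges$i, um3$edges$j), 20)
  expect_true(any(inc == 6))
  expect_true(all(um3$edges$distance >= 0))
})

test_that("two separated masses produce a U-matrix ridge between them", {
  set.seed(15)
  X <- rbind(matrix(rnorm(200, -4, 0.3), 100, 2),
             matrix(rnorm(200, 4, 0.3), 100, 2))
  fm <- as_fm(X)
  cb <- som_train(som_codebook(fm, rows = 3, cols = 6), fm, seed = 1)
  side <- ifelse(cb$codes[, 1] < 0, 1L, 2L)
  um <- compute_umatrix(cb)
  cross <- side[um$edges$i] != side[um$edges$j]
  expect_gt(min(um$edges$distance[cross]),
            max(um$edges$distance[!cross]))
})

test_that("codebook bundles round-trip through JSON", {
  set.seed(16)
  fm <- as_fm(matrix(rnorm(90), 30, 3))
  cb <- som_train(som_codebook(fm, rows = 2, cols = 3), fm, seed = 4)
  f <- tempfile(fileext = ".json")
  write_codebook(cb, f, fm = fm)
  back <- read_codebook(f)
  expect_equal(back$codebook$codes, cb$codes, tolerance = 1e-12)
  expect_equal(back$codebook$topology, cb$topology)
  expect_equal(back$codebook$lattice, cb$lattice)
  expect_equal(unlist(back$normalization$center),
               unname(fm$normalization$center), ignore_attr = TRUE)
})

test_that("invalid schedules are rejected", {
  fm <- as_fm(matrix(rnorm(40), 20, 2))
  cb <- som_codebook(fm, rows = 2, cols = 2)
  bad <- data.frame(t_max = 10, alpha0 = 0.1, alpha1 = 0.5,
                    sigma0 = 2, sigma1 = 1)
  expect_error(som_train(cb, fm, bad, seed = 1), "non-increasing")
  bad2 <- data.frame(t_max = 10, alpha0 = 0.5, alpha1 = -0.1,
                     sigma0 = 2, sigma1 = 1)
  expect_error(som_train(cb, fm, bad2, seed = 1), "positive")
})
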