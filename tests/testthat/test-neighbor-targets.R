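# Neighbourhood graphs and mean-image pseudo-supervision targets.

test_that("pairwise distances match a brute-force double loop", {
  s <- randomStack(10, 8, seed = 3)
  X <- matrix(pixels(s), ncol = 10)
  for (metric in c("euclidean", "correlation")) {
    D <- pairwiseDistances(s, metric)
    oracle <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10) {
      oracle[i, j] <- if (metric == "euclidean")
        sqrt(sum((X[, i] - X[, j])^2))
      else 1 - cor(X[, i], X[, j])
    }
    diag(oracle) <- 0
    expect_equal(D, oracle, tolerance = 1e-12)
    expect_equal(D, t(D))
    expect_equal(diag(D), rep(0, 10))
  }
})

test_that("simple closed-form distances hold", {
  a <- matrix(0.3, 8, 8)
  b <- a; b[2, 5] <- 0.3 + 0.25   # single pixel differs by 0.25
  s <- imageStack(array(c(a, b, a), c(8, 8, 3)))
  D <- pairwiseDistances(s, "euclidean")
  expect_equal(D[1, 2], 0.25)
  expect_equal(D[1, 3], 0)
})

test_that("correlation distance rejects constant images", {
  s <- imageStack(array(c(runif(64), rep(0.2, 64)), c(8, 8, 2)))
  expect_error(pairwiseDistances(s, "correlation"), "constant")
})

test_that("k nearest neighbours agree with full-sort brute force", {
  s <- randomStack(20, 8, seed = 5)
  D <- pairwiseDistances(s)
  g <- nearestNeighbors(D, neighborConfig(k = 5))
  for (i in 1:20) {
    expect_identical(g@indices[i, ], order(D[i, ])[1:5])
    expect_false(is.unsorted(g@distances[i, ]))
  }
  gx <- nearestNeighbors(D, neighborConfig(k = 5, includeSelf = FALSE))
  for (i in 1:20)
    expect_identical(gx@indices[i, ], setdiff(order(D[i, ]), i)[1:5])
})

test_that("self is the sole k = 1 neighbour, and small cases enumerate", {
  s <- randomStack(6, 8, seed = 6)
  D <- pairwiseDistances(s)
  g <- nearestNeighbors(D, neighborConfig(k = 1))
  expect_identical(g@indices[, 1], 1:6)
  expect_equal(g@distances[, 1], rep(0, 6))
  # three collinear images at mutual distances 1 and 2
  base <- matrix(0, 8, 8)
  mk <- function(v) { m <- base; m[1, 1] <- v; m }
  s3 <- imageStack(array(c(mk(0), mk(1), mk(2)), c(8, 8, 3)))
  D3 <- pairwiseDistances(s3)
  g3 <- nearestNeighbors(D3, neighborConfig(k = 2, includeSelf = FALSE))
  expect_identical(g3@indices[1, ], c(2L, 3L))
  expect_identical(g3@indices[2, ], c(1L, 3L))
  expect_identical(g3@indices[3, ], c(2L, 1L))
})

test_that("out-of-range k is rejected", {
  D <- pairwiseDistances(randomStack(4, 8))
  expect_error(nearestNeighbors(D, neighborConfig(k = 5)), "out of range")
  expect_error(nearestNeighbors(D, neighborConfig(k = 4, includeSelf = FALSE)),
               "out of range")
  expect_silent(nearestNeighbors(D, neighborConfig(k = 4)))
})

test_that("mean targets are convex combinations with passthrough labels", {
  s <- randomStack(9, 8, seed = 7)
  labels(s) <- rep(1:3, 3)
  g <- nearestNeighbors(pairwiseDistances(s), neighborConfig(k = 4))
  m <- meanTargets(s, g)
  expect_identical(labels(m), labels(s))
  for (i in 1:9) {
    contrib <- pixels(s)[, , g@indices[i, ]]
    expect_true(all(pixels(m)[, , i] >= apply(contrib, 1:2, min) - 1e-12))
    expect_true(all(pixels(m)[, , i] <= apply(contrib, 1:2, max) + 1e-12))
  }
  # k = 1 with self: the identity map
  g1 <- nearestNeighbors(pairwiseDistances(s), neighborConfig(k = 1))
  expect_equal(pixels(meanTargets(s, g1)), pixels(s))
  # identical neighbours: the mean IS that image
  dup <- imageStack(array(rep(pixels(s)[, , 1], 4), c(8, 8, 4)))
  gd <- nearestNeighbors(pairwiseDistances(dup), neighborConfig(k = 4))
  expect_equal(pixels(meanTargets(dup, gd))[, , 1], pixels(s)[, , 1])
})

test_that("averaging k noisy copies cuts noise variance by about 1/k", {
  k <- 16L
  clean <- matrix(runif(64), 8, 8)
  sigma <- 0.5
  ratios <- vapply(1:100, function(trial) {
    set.seed(trial)
    px <- array(clean, c(8, 8, k)) + array(rnorm(64 * k, sd = sigma), c(8, 8, k))
    s <- imageStack(px)
    g <- nearestNeighbors(pairwiseDistances(s), neighborConfig(k = k))
    m <- meanTargets(s, g)
    mean((pixels(m)[, , 1] - clean)^2) / sigma^2
  }, numeric(1))
  expect_lt(abs(mean(ratios) / (1 / k) - 1), 0.2)
})

test_that("neighbours of clean class-structured images stay in class", {
  plan <- tinyPlan(nPerClass = 30L, side = 32L, seed = 37L)
  ds <- buildDatasets(plan)
  clean <- imageStack(cleanRef(ds$test), labels = labels(ds$test))
  g <- nearestNeighbors(pairwiseDistances(clean),
                        neighborConfig(k = 5, includeSelf = FALSE))
  sameClass <- mean(vapply(seq_len(nImages(clean)), function(i)
    mean(labels(clean)[g@indices[i, ]] == labels(clean)[i]), numeric(1)))
  expect_gt(sameClass, 0.25)
})

test_that("neighbour graphs round-trip through their text serialization", {
  s <- randomStack(12, 8, seed = 8)
  g <- nearestNeighbors(pairwiseDistances(s), neighborConfig(k = 3))
  f <- tempfile()
  writeNeighborGraph(g, f)
  g2 <- readNeighborGraph(f)
  expect_identical(g2@indices, g@indices)
  expect_equal(g2@distances, g@distances, tolerance = 1e-12)
})
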