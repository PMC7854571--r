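# The single convolutional denoising autoencoder block.

test_that("blocks preserve image shape and reject indivisible sides", {
  spec <- tinySpec()
  b <- buildBlock(spec, seed = 1)
  for (side in c(64L, 48L)) {
    s <- randomStack(2, side)
    out <- applyBlock(b, s)
    expect_identical(imageDim(out), c(side, side))
    expect_identical(nImages(out), 2L)
  }
  bad <- array(runif(50 * 50 * 2), c(50, 50, 2))
  expect_error(applyBlock(b, bad), "divisible")
})

test_that("parameter initialization is seed-deterministic", {
  expect_identical(buildBlock(tinySpec(), seed = 5)@params,
                   buildBlock(tinySpec(), seed = 5)@params)
  expect_false(identical(buildBlock(tinySpec(), seed = 5)@params,
                         buildBlock(tinySpec(), seed = 6)@params))
})

test_that("parameter count matches the layer-by-layer arithmetic oracle", {
  for (spec in list(blockSpec(), blockSpec(channels = 8),
                    blockSpec(channels = 4, encoderModules = 2,
                              convsPerModule = 1, kernelSide = 5))) {
    C <- spec@channels; k <- spec@kernelSide
    # oracle: walk the architecture independently
    count <- 0L
    cin <- 1L
    for (m in seq_len(spec@encoderModules))
      for (v in seq_len(spec@convsPerModule)) {
        count <- count + C * (cin * k^2 + 1L)
        cin <- C
      }
    for (m in seq_len(spec@encoderModules))
      count <- count + C * (C * k^2 + 1L)
    count <- as.integer(count + 1L * (C * k^2 + 1L))
    expect_identical(nParams(spec), count)
    # and the actual parameter tensors carry exactly that many numbers
    b <- buildBlock(spec, seed = 1)
    actual <- sum(vapply(b@params,
                         function(l) length(l$W) + length(l$b), numeric(1)))
    expect_identical(as.integer(actual), count)
  }
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(2)
  C <- 2L; E <- 2L; V <- 1L; K <- 3L; H <- 8L
  x <- array(runif(H * H * 3), c(H, H, 3))
  t <- array(runif(H * H * 3), c(H, H, 3))
  p <- cryocascade:::.cae_init(C, E, V, K, 5L)
  g <- cryocascade:::.cae_loss_grad(p, x, t, C, E, V, K, 2L)
  eps <- 3e-3
  rels <- c()
  for (l in seq_along(p)) {
    for (idx in sample(length(p[[l]]$W), 8)) {
      p2 <- p; p2[[l]]$W[idx] <- p2[[l]]$W[idx] + eps
      lp <- cryocascade:::.cae_loss_grad(p2, x, t, C, E, V, K, 2L)$loss
      p2[[l]]$W[idx] <- p2[[l]]$W[idx] - 2 * eps
      lm <- cryocascade:::.cae_loss_grad(p2, x, t, C, E, V, K, 2L)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- g$grads[[l]]$W[idx]
      rels <- c(rels, abs(num - ana) / max(1e-4, abs(num) + abs(ana)))
    }
  }
  # float32 forward noise and ReLU kinks allow isolated outliers; the
  # typical agreement must be tight
  expect_lt(mean(rels), 0.01)
  expect_lt(max(rels), 0.1)
})

test_that("training learns the identity on constant images", {
  # dropout off: the recorded training loss is then the true
  # reconstruction error, which must vanish on this trivial task
  s <- imageStack(array(0.5, c(16, 16, 16)))
  b <- buildBlock(blockSpec(channels = 4, dropoutRate = 0), seed = 1)
  b <- trainBlock(b, s, s, trainConfig(epochs = 50, batchSize = 2,
                                       learningRate = 1e-3, seed = 1))
  expect_length(b@lossHistory, 50L)
  expect_lt(tail(b@lossHistory, 1), 1e-3)
  # self-supervised training never drifts far above its best epoch
  expect_lte(tail(b@lossHistory, 1), 1.5 * min(b@lossHistory))
})

test_that("training on noisy-to-clean pairs reduces the loss", {
  plan <- tinyPlan(nPerClass = 25L, side = 32L, seed = 17L)
  ds <- buildDatasets(plan)
  b <- buildBlock(tinySpec(8L), seed = 2)
  b <- trainBlock(b, ds$train$mid, ds$train$clean,
                  trainConfig(epochs = 6, seed = 3))
  expect_lt(tail(b@lossHistory, 1), b@lossHistory[1])
})

test_that("mismatched input/target stacks are rejected", {
  b <- buildBlock(tinySpec(), seed = 1)
  expect_error(trainBlock(b, randomStack(4), randomStack(5), trainConfig()),
               "identical length")
})

test_that("zero-epoch training is a no-op", {
  b <- buildBlock(tinySpec(), seed = 1)
  s <- randomStack(3, 16)
  b2 <- trainBlock(b, s, s, trainConfig(epochs = 0))
  expect_identical(b2@params, b@params)
  expect_length(b2@lossHistory, 0L)
})

test_that("inference is deterministic and passes metadata through", {
  b <- buildBlock(tinySpec(), seed = 4)
  s <- randomStack(5, 16)
  labels(s) <- c(1L, 1L, 2L, 2L, 3L)
  o1 <- applyBlock(b, s)
  o2 <- applyBlock(b, s)
  expect_identical(o1@pixels, o2@pixels)
  expect_identical(labels(o1), labels(s))
})

test_that("a trained block denoises held-out images of the same phantom", {
  plan <- tinyPlan(nPerClass = 30L, side = 32L, seed = 23L)
  ds <- buildDatasets(plan)
  n <- nImages(ds$train$mid)
  set.seed(1)
  holdout <- sort(sample(n, 20))
  trainIdx <- setdiff(seq_len(n), holdout)
  b <- buildBlock(tinySpec(8L), seed = 5)
  b <- trainBlock(b, ds$train$mid[trainIdx], ds$train$clean[trainIdx],
                  trainConfig(epochs = 10, seed = 6))
  held <- ds$train$mid[holdout]
  denoised <- applyBlock(b, held)
  expect_gt(psnrVsClean(held, pixels(denoised))@meanDb,
            psnrVsClean(held)@meanDb)
})

test_that("serialized blocks restore bit-identical inference", {
  plan <- tinyPlan(nPerClass = 6L, side = 32L, seed = 31L)
  ds <- buildDatasets(plan)
  b <- buildBlock(tinySpec(), seed = 7)
  b <- trainBlock(b, ds$train$low, ds$train$mid,
                  trainConfig(epochs = 2, seed = 8))
  f <- tempfile(fileext = ".rds")
  writeBlock(b, f)
  b2 <- readBlock(f)
  s <- randomStack(3, 32, seed = 2)
  expect_identical(pixels(applyBlock(b2, s)), pixels(applyBlock(b, s)))
})

test_that("reading a corrupted weights file fails loudly", {
  f <- tempfile(fileext = ".rds")
  saveRDS(list(garbage = TRUE), f)
  expect_error(readBlock(f), "TrainedBlock")
})
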