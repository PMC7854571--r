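# Cascade orchestration: tiered pre-training, sequential fine-tuning,
# end-to-end denoising.  Uses a light architecture and short training so
# each property stays cheap; the full-size experiment lives in the
# acceptance suite.

smallCascadeFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    plan <- tinyPlan(nPerClass = 25L, side = 32L, seed = 43L)
    ds <- buildDatasets(plan)
    model <- pretrainCascade(ds$train, tinySpec(8L),
                             trainConfig(epochs = 8, seed = 101),
                             neighborCfg = neighborConfig(k = 10))
    cache <<- list(ds = ds, model = model)
    cache
  }
})

test_that("pre-training requires aligned tiers and trains every block", {
  fx <- smallCascadeFixture()
  model <- fx$model
  expect_length(model@blocks, 3L)
  expect_true(model@pretrained)
  for (b in model@blocks) {
    expect_length(b@lossHistory, 8L)
    expect_lt(tail(b@lossHistory, 1), b@lossHistory[1])
  }
  bad <- fx$ds$train
  bad$mid <- bad$mid[1:10]
  expect_error(pretrainCascade(bad, tinySpec(8L), trainConfig(epochs = 1)),
               "misaligned")
})

test_that("the pre-trained cascade already denoises held-out noisy images", {
  fx <- smallCascadeFixture()
  out <- denoise(fx$model, fx$ds$test, enhance = FALSE)
  expect_gt(psnrVsClean(fx$ds$test, pixels(out))@meanDb,
            psnrVsClean(fx$ds$test)@meanDb)
})

test_that("zero-epoch fine-tuning is a no-op and bookkeeping is consistent", {
  fx <- smallCascadeFixture()
  res <- finetuneCascade(fx$model, fx$ds$test, trainConfig(epochs = 0))
  for (j in 1:3)
    expect_identical(res$model@blocks[[j]]@params, fx$model@blocks[[j]]@params)
  # final output equals plain denoising with the pre-trained cascade
  expect_equal(pixels(res$record@stacks$final),
               pixels(denoise(fx$model, fx$ds$test)))
  # record stages match manual recomputation
  expect_identical(pixels(res$record@stacks$X1), pixels(fx$ds$test))
  expect_equal(pixels(res$record@stacks$X2),
               pixels(applyBlock(res$model@blocks[[1]], fx$ds$test)))
})

test_that("fine-tuning updates blocks and records stage stacks", {
  fx <- smallCascadeFixture()
  res <- finetuneCascade(fx$model, fx$ds$test,
                         trainConfig(epochs = 3, seed = 77))
  expect_false(identical(res$model@blocks[[1]]@params,
                         fx$model@blocks[[1]]@params))
  expect_named(res$record@stacks, c("X1", "X2", "X3", "X4", "final"))
  ns <- vapply(res$record@stacks, nImages, integer(1))
  expect_true(all(ns == nImages(fx$ds$test)))
  for (lh in res$record@lossHistories) expect_length(lh, 3L)
  # X2 recomputes from the fine-tuned block 1
  expect_equal(pixels(res$record@stacks$X2),
               pixels(applyBlock(res$model@blocks[[1]], fx$ds$test)))
  # both target modes run; recomputing targets per block yields a
  # different (but valid) cascade than the default fixed-target mode
  res2 <- finetuneCascade(fx$model, fx$ds$test,
                          trainConfig(epochs = 3, seed = 77),
                          targetMode = "per_block")
  expect_false(identical(pixels(res2$record@stacks$X4),
                         pixels(res$record@stacks$X4)))
  # neighbourhood graphs computed on the raw inputs instead of the block
  # outputs: a supported variant that changes the targets
  res3 <- finetuneCascade(fx$model, fx$ds$test,
                          trainConfig(epochs = 1, seed = 77),
                          neighborOn = "input")
  expect_identical(nImages(res3$record@stacks$final), nImages(fx$ds$test))
})

test_that("fine-tuning an untrained cascade is a state error", {
  blocks <- lapply(1:3, function(j) buildBlock(tinySpec(), seed = j))
  model <- new("CascadeModel", blocks = blocks,
               neighborCfg = neighborConfig(k = 3), enhance = TRUE,
               targetMode = "per_block", pretrained = FALSE)
  expect_error(finetuneCascade(model, randomStack(8, 16), trainConfig()),
               "pre-trained")
  expect_error(denoise(model, randomStack(8, 16)), "pre-trained")
})

test_that("denoise equals the manual block chain plus equalization", {
  fx <- smallCascadeFixture()
  out <- denoise(fx$model, fx$ds$test)
  X <- fx$ds$test
  for (b in fx$model@blocks) X <- applyBlock(b, X)
  expect_equal(pixels(out), pixels(histogramEqualize(X)))
  expect_equal(pixels(denoise(fx$model, fx$ds$test, enhance = FALSE)),
               pixels(X))
  # determinism
  expect_identical(pixels(denoise(fx$model, fx$ds$test)), pixels(out))
})

test_that("near-identity blocks reproduce a constant stack through the cascade", {
  s <- imageStack(array(0.5, c(16, 16, 10)))
  blocks <- lapply(1:3, function(j) {
    b <- buildBlock(blockSpec(channels = 4, dropoutRate = 0), seed = j)
    trainBlock(b, s, s, trainConfig(epochs = 120, batchSize = 2,
                                    learningRate = 1e-3, seed = j))
  })
  model <- new("CascadeModel", blocks = blocks,
               neighborCfg = neighborConfig(k = 3), enhance = FALSE,
               targetMode = "per_block", pretrained = TRUE)
  err <- abs(pixels(denoise(model, s)) - pixels(s))
  # zero-padded convolutions leave a thin border halo, so the identity
  # check applies to the interior plus a mean bound overall
  expect_lt(max(err[4:13, 4:13, ]), 0.05)
  expect_lt(mean(err), 0.05)
})
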