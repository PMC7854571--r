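# Phantom generation, projection geometry, and SNR-calibrated simulation.

test_that("makePhantom is deterministic, normalized, and validates arguments", {
  v1 <- makePhantom(32, nComponents = 1, seed = 7)
  v2 <- makePhantom(32, nComponents = 1, seed = 7)
  expect_identical(v1@grid, v2@grid)
  expect_equal(max(v1@grid), 1)
  expect_true(all(v1@grid >= 0))
  expect_error(makePhantom(32, nComponents = 0, seed = 1), "nComponents")
  expect_error(makePhantom(8, nComponents = 1, seed = 1), "side")
})

test_that("phantom density is the normalized sum of its component masses", {
  vol <- makePhantom(64, nComponents = 5, seed = 1)
  # independent oracle: re-evaluate every component by direct voxel
  # summation from the stored descriptors
  side <- vol@side
  ax <- seq_len(side)
  p <- rbind(rep(ax, times = side^2),
             rep(rep(ax, each = side), times = side),
             rep(ax, each = side^2))
  total <- 0
  raw <- numeric(side^3)
  for (cmp in vol@components) {
    q <- diag(1 / cmp$axes) %*% cmp$rotation %*% (p - cmp$center)
    r2 <- colSums(q * q)
    v <- if (cmp$type == "gaussian") cmp$amplitude * exp(-0.5 * r2)
         else cmp$amplitude * (r2 <= 1)
    total <- total + sum(v)
    raw <- raw + v
  }
  # total mass of the (unnormalized) grid equals the sum of component masses
  expect_equal(sum(vol@grid) * max(raw), total, tolerance = 1e-10)
})

test_that("identity-orientation projection is the plain z-axis sum", {
  vol <- makePhantom(32, 2, seed = 3)
  expect_equal(projectVolume(vol, c(0, 0, 0)), rowSums(vol@grid, dims = 2))
})

test_that("projections of a spherical phantom are orientation-invariant", {
  vol <- sphericalPhantom(64, sd = 8)
  ref <- projectVolume(vol, c(0, 0, 0))
  for (o in list(c(33, 61, 17), c(120, 45, 77), c(10, 90, 0))) {
    expect_lt(max(abs(projectVolume(vol, o) - ref)) / max(ref), 0.01)
  }
})

test_that("a 90-degree in-plane rotation rotates the projection image", {
  vol <- offCenterPhantom(32)
  p0 <- projectVolume(vol, c(0, 0, 0))
  p90 <- projectVolume(vol, c(90, 0, 0))
  side <- vol@side
  expect_equal(p90, t(p0)[side:1, ], tolerance = 1e-8)
})

test_that("noise sigma follows sqrt(pooledVar / snr) and rejects flat stacks", {
  # half the pixels 0, half 0.4: pooled variance exactly 0.04
  px <- array(rep(c(0, 0.4), each = 32), c(8, 8, 4))
  s <- imageStack(px)
  expect_equal(calibrateNoiseSigma(s, snrLevel(0.1, "low")), sqrt(0.4))
  expect_equal(calibrateNoiseSigma(s, snrLevel(0.4, "mid")), sqrt(0.1))
  flat <- imageStack(array(0.5, c(8, 8, 3)))
  expect_error(calibrateNoiseSigma(flat, snrLevel(0.1, "low")), "degenerate")
  expect_error(calibrateNoiseSigma(s, snrLevel(Inf, "clean")), "clean")
})

test_that("addNoise realizes the target SNR, is seeded, and vanishes as snr -> Inf", {
  plan <- tinyPlan(nPerClass = 30L, side = 64L, seed = 5L)
  clean <- cryocascade:::projectClasses(plan@phantom, plan@orientations, 30L)
  for (tier in list(snrLevel(0.1, "low"), snrLevel(0.4, "mid"),
                    snrLevel(0.6, "high"))) {
    noisy <- addNoise(clean, tier, seed = 21)
    ratio <- mean((noisy@pixels - clean@pixels)^2) / tier@value^-1 /
      mean((clean@pixels - mean(clean@pixels))^2)
    expect_lt(abs(ratio - 1), 0.05)
    expect_identical(noisy@cleanRef, clean@pixels)
    expect_identical(snrTag(noisy)$tier, tier@tier)
  }
  n1 <- addNoise(clean, snrLevel(0.1, "low"), seed = 21)
  n2 <- addNoise(clean, snrLevel(0.1, "low"), seed = 21)
  expect_identical(n1@pixels, n2@pixels)
  faint <- addNoise(clean, snrLevel(1e9, "high"), seed = 3)
  expect_lt(max(abs(faint@pixels - clean@pixels)), 1e-3)
})

test_that("addNoise stores unclipped values", {
  clean <- imageStack(array(rep(c(0, 1), each = 32), c(8, 8, 20)))
  noisy <- addNoise(clean, snrLevel(0.1, "low"), seed = 1)
  expect_true(any(noisy@pixels < 0) || any(noisy@pixels > 1))
})

test_that("buildDatasets yields the canonical counts at full replication", {
  # 4 orientations x 1,000 images x 4 tiers = 16,000 training images;
  # the test stack has 4 x 1,000 = 4,000 (exercised at image side 16)
  plan <- simulationPlan(nPerClass = 1000L, imageSide = 16L, seed = 2L)
  ds <- buildDatasets(plan)
  expect_identical(sum(vapply(ds$train, nImages, integer(1))), 16000L)
  expect_identical(nImages(ds$test), 4000L)
  expect_identical(snrTag(ds$test)$value, 0.1)
})

test_that("tiers are index-aligned and the test stack uses a distinct phantom", {
  plan <- tinyPlan(nPerClass = 50L, side = 32L, seed = 4L)
  ds <- buildDatasets(plan)
  expect_identical(sum(vapply(ds$train, nImages, integer(1))), 800L)
  # clean tier image i IS the clean reference of every noisy tier's image i
  expect_identical(ds$train$clean@pixels, ds$train$low@cleanRef)
  expect_identical(ds$train$clean@pixels, ds$train$mid@cleanRef)
  expect_identical(ds$train$clean@pixels, ds$train$high@cleanRef)
  expect_identical(labels(ds$train$low), labels(ds$train$clean))
  # different phantom for testing
  expect_false(identical(plan@phantom@grid, plan@testPhantom@grid))
  expect_false(identical(ds$test@cleanRef[, , 1], ds$train$clean@pixels[, , 1]))
  # clean tier normalized to [0, 1]
  expect_equal(range(ds$train$clean@pixels), c(0, 1))
})

test_that("identical plans reproduce identical datasets byte for byte", {
  plan1 <- tinyPlan(nPerClass = 5L, side = 32L, seed = 9L)
  plan2 <- tinyPlan(nPerClass = 5L, side = 32L, seed = 9L)
  ds1 <- buildDatasets(plan1)
  ds2 <- buildDatasets(plan2)
  expect_identical(lapply(ds1$train, pixels), lapply(ds2$train, pixels))
  expect_identical(ds1$test@pixels, ds2$test@pixels)
  f1 <- tempfile(); f2 <- tempfile()
  writeStack(ds1$test, f1); writeStack(ds2$test, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("per-class means of noisy images converge to the clean projection", {
  n <- 100L
  plan <- tinyPlan(nPerClass = n, side = 32L, seed = 13L)
  ds <- buildDatasets(plan)
  noisy <- ds$train$low
  sigma2 <- calibrateNoiseSigma(ds$train$clean, snrLevel(0.1, "low"))^2
  for (cls in 1:2) {
    sel <- which(labels(noisy) == cls)
    avg <- rowMeans(noisy@pixels[, , sel], dims = 2)
    clean <- ds$train$clean@pixels[, , sel[1]]
    residVar <- mean((avg - clean)^2)
    expect_lt(abs(residVar / (sigma2 / n) - 1), 0.15)
  }
})
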