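## Noise calibration and tiered dataset simulation.

#' Calibrate the Gaussian noise level for a target SNR
#'
#' With SNR defined as signal pixel variance over noise pixel variance,
#' the standard deviation of the additive noise that realizes a target SNR
#' on a given clean stack is `sqrt(pooledVar / snr)`, where `pooledVar` is
#' the pixel variance pooled over the whole stack.
#'
#' @param cleanImages a clean [ImageStack-class] (or `(H, W, N)` array).
#' @param snr an [SNRLevel-class] with a non-clean tier.
#' @return The positive noise standard deviation.
#' @examples
#' s <- imageStack(array(rep(c(0, 0.4), each = 128), c(16, 16, 1)))
#' calibrateNoiseSigma(s, snrLevel(0.1, "low"))  # sqrt(0.04 / 0.1)
#' @export
calibrateNoiseSigma <- function(cleanImages, snr) {
  stopifnot(is(snr, "SNRLevel"))
  if (snr@tier == "clean") stop("cannot calibrate noise for the clean tier")
  px <- asPixelArray(cleanImages)
  if (length(px) == 0L) stop("clean stack is empty")
  v <- mean((px - mean(px))^2)  # pooled (population) pixel variance
  if (v < 1e-12) stop("degenerate signal: the clean stack has zero variance")
  sqrt(v / snr@value)
}

#' Corrupt a clean stack with SNR-calibrated Gaussian noise
#'
#' Adds per-pixel i.i.d. zero-mean Gaussian noise with the standard
#' deviation from [calibrateNoiseSigma()].  Noisy values are stored
#' unclipped (values outside `[0, 1]` are preserved; clipping happens only
#' on export to 8-bit formats), the input becomes the `cleanRef` of the
#' result, and the SNR tag is set.
#'
#' @param clean a clean [ImageStack-class].
#' @param snr an [SNRLevel-class] with a non-clean tier.
#' @param seed integer; the noise is deterministic given the seed.
#' @return A noisy [ImageStack-class] with `cleanRef` and SNR tag set.
#' @examples
#' vol <- makePhantom(16, 2, seed = 1)
#' img <- projectVolume(vol, c(0, 0, 0))
#' s <- imageStack(array(img / max(img), c(16, 16, 1)))
#' noisy <- addNoise(s, snrLevel(0.4, "mid"), seed = 3)
#' @export
addNoise <- function(clean, snr, seed = 1L) {
  stopifnot(is(clean, "ImageStack"))
  sigma <- calibrateNoiseSigma(clean, snr)
  px <- clean@pixels
  noise <- withSeed(seed, rnorm(length(px), sd = sigma))
  new("ImageStack", pixels = px + array(noise, dim(px)),
      labels = clean@labels, snrValue = snr@value, snrTier = snr@tier,
      cleanRef = px)
}

#' Construct a simulation plan
#'
#' A plan fixes everything needed to simulate one tiered dataset: the
#' training and test phantoms, the viewing orientations, the number of
#' replicate images per orientation class, the SNR tiers and the seed.
#' The defaults are the canonical study conditions: 4 orientations,
#' 1,000 images per class per tier, SNR tiers 0.1 / 0.4 / 0.6 / clean.
#' The test phantom defaults to a fresh phantom drawn with a distinct
#' seed, mirroring a train-on-one-structure / test-on-another split.
#'
#' @param phantom training [PhantomVolume-class]; defaults to
#'   `makePhantom(imageSide, seed = ...)`.
#' @param testPhantom test [PhantomVolume-class]; defaults to
#'   a fresh phantom at a derived seed.
#' @param orientations `(n, 3)` matrix of ZYZ Euler angles in degrees.
#' @param nPerClass images per orientation class per tier.
#' @param snrTiers list of four [SNRLevel-class] tiers, ordered
#'   low/mid/high/clean.
#' @param imageSide image (and phantom) side in pixels; must be divisible
#'   by 8.
#' @param seed integer global seed.
#' @return A [SimulationPlan-class].
#' @examples
#' plan <- simulationPlan(nPerClass = 10, imageSide = 32, seed = 1)
#' @export
simulationPlan <- function(phantom = NULL, testPhantom = NULL,
                           orientations = defaultOrientations(),
                           nPerClass = 1000L,
                           snrTiers = defaultSnrTiers(),
                           imageSide = 64L, seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(phantom))
    phantom <- makePhantom(imageSide, seed = deriveSeed(seed, "train_phantom"))
  if (is.null(testPhantom))
    testPhantom <- makePhantom(imageSide, seed = deriveSeed(seed, "test_phantom"))
  new("SimulationPlan", phantom = phantom, testPhantom = testPhantom,
      orientations = orientations, nPerClass = as.integer(nPerClass),
      snrTiers = snrTiers, imageSide = as.integer(imageSide), seed = seed)
}

# Project a phantom at each orientation, min-max normalize to [0, 1] using
# the range over all (clean) projections, and replicate each class.
projectClasses <- function(phantom, orientations, nPerClass) {
  projs <- lapply(seq_len(nrow(orientations)), function(i)
    projectVolume(phantom, orientations[i, ]))
  lo <- min(vapply(projs, min, numeric(1)))
  hi <- max(vapply(projs, max, numeric(1)))
  projs <- lapply(projs, function(p) (p - lo) / (hi - lo))
  side <- dim(projs[[1]])[1]
  n <- length(projs) * nPerClass
  px <- array(0, c(side, side, n))
  for (i in seq_along(projs))
    px[, , (i - 1) * nPerClass + seq_len(nPerClass)] <- projs[[i]]
  imageStack(px, labels = rep(seq_along(projs), each = nPerClass))
}

#' Simulate the tiered training stacks and the test stack
#'
#' Builds four index-aligned training stacks -- the same underlying clean
#' projections of the training phantom corrupted at the low, mid and high
#' SNR tiers, plus the clean tier itself -- so that image `i` shares one
#' clean source across tiers, and (input, target) pairs for pre-training
#' are formed by index.  The test stack projects the distinct test phantom
#' and is corrupted at the low tier only, carrying labels and clean
#' references for evaluation.
#'
#' @param plan a [SimulationPlan-class].
#' @return A list with elements `train` (a named list of [ImageStack-class]
#'   objects `low`, `mid`, `high`, `clean`) and `test` (an
#'   [ImageStack-class]).
#' @examples
#' plan <- simulationPlan(nPerClass = 5, imageSide = 32, seed = 1)
#' ds <- buildDatasets(plan)
#' nImages(ds$train$low)   # 4 classes x 5
#' @export
buildDatasets <- function(plan) {
  stopifnot(is(plan, "SimulationPlan"))
  trainClean <- projectClasses(plan@phantom, plan@orientations, plan@nPerClass)
  tiers <- plan@snrTiers
  train <- list(
    low = addNoise(trainClean, tiers$low, deriveSeed(plan@seed, "train_low")),
    mid = addNoise(trainClean, tiers$mid, deriveSeed(plan@seed, "train_mid")),
    high = addNoise(trainClean, tiers$high, deriveSeed(plan@seed, "train_high")),
    clean = {
      cl <- trainClean
      cl@snrValue <- Inf
      cl@snrTier <- "clean"
      cl@cleanRef <- cl@pixels
      cl
    })
  testClean <- projectClasses(plan@testPhantom, plan@orientations,
                              plan@nPerClass)
  test <- addNoise(testClean, tiers$low, deriveSeed(plan@seed, "test_low"))
  list(train = train, test = test)
}

#' Empirical SNR of a noisy stack against its clean counterpart
#'
#' Pooled pixel variance of the clean stack divided by the pooled variance
#' of the residual (noisy minus clean).  Validates that simulated stacks
#' realize their target tier.  `Inf` when the stacks are identical.
#'
#' @param clean clean [ImageStack-class] or array.
#' @param noisy noisy [ImageStack-class] or array of the same dimensions.
#' @return Numeric SNR estimate.
#' @examples
#' plan <- simulationPlan(nPerClass = 25, imageSide = 32, seed = 1)
#' ds <- buildDatasets(plan)
#' empiricalSNR(cleanRef(ds$test), ds$test)   # close to 0.1
#' @export
empiricalSNR <- function(clean, noisy) {
  cl <- asPixelArray(clean)
  no <- asPixelArray(noisy)
  if (!identical(dim(cl), dim(no)))
    stop("clean and noisy stacks must have identical dimensions")
  resid <- no - cl
  vNoise <- mean((resid - mean(resid))^2)
  vSignal <- mean((cl - mean(cl))^2)
  if (vNoise == 0) return(Inf)
  vSignal / vNoise
}
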