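## S4 class definitions and constructors for the package's containers.

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' ImageStack: an ordered collection of same-sized grayscale images
#'
#' The central container of the package: a stack of 2D grayscale projection
#' images stored as an `(H, W, N)` array, with optional per-image orientation
#' class labels, an optional SNR tag describing the noise tier the stack was
#' simulated at, and an optional parallel stack of noise-free counterparts.
#' Clean stacks are min-max normalized to `[0, 1]`; noisy pixel values may
#' exceed that range and are stored unclipped (clipping happens only on
#' export to 8-bit formats).
#'
#' Image sides must be at least 8 and divisible by 8, so that three rounds of
#' 2x2 pooling are well-defined.
#'
#' @slot pixels numeric `(H, W, N)` array of pixel values.
#' @slot labels integer vector of per-image orientation class indices
#'   (length `N`), or `integer(0)` when unlabeled.
#' @slot snrValue numeric; target signal-variance / noise-variance ratio of
#'   the stack, `NA` if untagged, `Inf` for a clean tier.
#' @slot snrTier character; one of `"low"`, `"mid"`, `"high"`, `"clean"`, or
#'   `NA` if untagged.
#' @slot cleanRef `(H, W, N)` array of noise-free counterparts, or `NULL`.
#'
#' @seealso [imageStack()], [nImages()], [buildDatasets()]
#' @export
setClass("ImageStack",
  representation(pixels = "array", labels = "integer",
                 snrValue = "numeric", snrTier = "character",
                 cleanRef = "arrayOrNULL"),
  prototype(labels = integer(0), snrValue = NA_real_,
            snrTier = NA_character_, cleanRef = NULL))

setValidity("ImageStack", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L)
    return("'pixels' must be an (H, W, N) array")
  if (d[1] < 8L || d[2] < 8L || d[1] %% 8L != 0L || d[2] %% 8L != 0L)
    return("image sides must be >= 8 and divisible by 8")
  if (length(object@labels) && length(object@labels) != d[3])
    return("'labels' length must equal the number of images")
  if (!is.null(object@cleanRef) && !identical(dim(object@cleanRef), d))
    return("'cleanRef' must have the same dimensions as 'pixels'")
  if (anyNA(object@pixels))
    return("'pixels' must not contain NA")
  TRUE
})

#' Construct an ImageStack
#'
#' @param pixels an `(H, W, N)` numeric array, or an `(H, W)` matrix for a
#'   single-image stack.
#' @param labels optional integer vector of per-image class labels.
#' @param snr optional [SNRLevel-class] tag.
#' @param cleanRef optional `(H, W, N)` array of noise-free counterparts.
#' @return An [ImageStack-class] object.
#' @examples
#' s <- imageStack(array(runif(16 * 16 * 5), c(16, 16, 5)), labels = rep(1L, 5))
#' nImages(s)
#' @export
imageStack <- function(pixels, labels = NULL, snr = NULL, cleanRef = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  new("ImageStack",
      pixels = pixels,
      labels = if (is.null(labels)) integer(0) else as.integer(labels),
      snrValue = if (is.null(snr)) NA_real_ else snr@value,
      snrTier = if (is.null(snr)) NA_character_ else snr@tier,
      cleanRef = cleanRef)
}

#' SNRLevel: a calibrated noise tier
#'
#' The signal-to-noise ratio used throughout the package is the ratio of
#' signal pixel variance (pooled over a clean stack) to noise pixel
#' variance.  The canonical simulation tiers are low = 0.1, mid = 0.4,
#' high = 0.6, plus a noise-free "clean" tier.
#'
#' @slot value positive numeric SNR; `Inf` for the clean tier.
#' @slot tier one of `"low"`, `"mid"`, `"high"`, `"clean"`.
#' @seealso [snrLevel()], [defaultSnrTiers()]
#' @export
setClass("SNRLevel", representation(value = "numeric", tier = "character"))

setValidity("SNRLevel", function(object) {
  if (!object@tier %in% c("low", "mid", "high", "clean"))
    return("tier must be one of low/mid/high/clean")
  if (object@tier == "clean") {
    if (is.finite(object@value)) return("clean tier must have value Inf")
  } else if (!is.finite(object@value) || object@value <= 0) {
    return("SNR value must be a positive finite number")
  }
  TRUE
})

#' @param value positive SNR (signal variance / noise variance); ignored and
#'   set to `Inf` when `tier = "clean"`.
#' @param tier noise tier name.
#' @return An [SNRLevel-class].
#' @examples
#' snrLevel(0.1, "low")
#' @rdname SNRLevel-class
#' @export
snrLevel <- function(value, tier) {
  if (identical(tier, "clean")) value <- Inf
  new("SNRLevel", value = as.numeric(value), tier = tier)
}

#' The canonical simulation tiers
#'
#' Low, mid and high SNR set to 0.1, 0.4 and 0.6 respectively, plus the
#' noise-free tier -- the conditions the simulator emulates.
#'
#' @return A named list of four [SNRLevel-class] objects.
#' @export
defaultSnrTiers <- function() {
  list(low = snrLevel(0.1, "low"), mid = snrLevel(0.4, "mid"),
       high = snrLevel(0.6, "high"), clean = snrLevel(Inf, "clean"))
}

#' PhantomVolume: a synthetic 3D density
#'
#' A cubic grid of non-negative densities built as a sum of random
#' anisotropic Gaussian blobs and/or solid ellipsoids, standing in for a
#' macromolecular 3D structure.  Projections of the phantom at fixed
#' orientations provide clean reference images for simulation.
#'
#' @slot grid numeric `(side, side, side)` array, values in `[0, 1]`.
#' @slot side integer edge length in voxels (at least 16).
#' @slot components list of component descriptors (type, center, axes,
#'   rotation, amplitude).
#' @seealso [makePhantom()], [projectVolume()]
#' @export
setClass("PhantomVolume",
  representation(grid = "array", side = "integer", components = "list"))

setValidity("PhantomVolume", function(object) {
  if (object@side < 16L) return("side must be at least 16")
  if (!identical(dim(object@grid), rep(object@side, 3L)))
    return("grid must be a (side, side, side) array")
  if (any(object@grid < 0)) return("densities must be non-negative")
  if (length(object@components) < 1L)
    return("at least one component is required")
  TRUE
})

#' SimulationPlan: everything needed to simulate one tiered dataset
#'
#' @slot phantom the [PhantomVolume-class] projected for the training tiers.
#' @slot testPhantom a distinct phantom projected for the test stack,
#'   mirroring a train-on-one-protein / test-on-another split.
#' @slot orientations numeric `(n_classes, 3)` matrix of ZYZ Euler angles in
#'   degrees; rows must be pairwise distinct.
#' @slot nPerClass integer; images per orientation class per tier.
#' @slot snrTiers list of four [SNRLevel-class] tiers (low, mid, high, clean).
#' @slot imageSide integer; equals the phantom side.
#' @slot seed integer seed from which all per-stage noise seeds are derived.
#' @seealso [simulationPlan()], [buildDatasets()]
#' @export
setClass("SimulationPlan",
  representation(phantom = "PhantomVolume", testPhantom = "PhantomVolume",
                 orientations = "matrix", nPerClass = "integer",
                 snrTiers = "list", imageSide = "integer", seed = "integer"))

setValidity("SimulationPlan", function(object) {
  if (object@nPerClass < 1L) return("nPerClass must be >= 1")
  if (ncol(object@orientations) != 3L)
    return("orientations must be an (n, 3) matrix of ZYZ Euler angles")
  if (anyDuplicated(object@orientations))
    return("orientations must be pairwise distinct")
  if (!all(is.finite(object@orientations)))
    return("orientation angles must be finite")
  if (object@imageSide != object@phantom@side)
    return("imageSide must equal the phantom side")
  if (object@testPhantom@side != object@phantom@side)
    return("test phantom must have the same side as the training phantom")
  if (length(object@snrTiers) != 4L)
    return("snrTiers must list the low, mid, high and clean tiers")
  tiers <- vapply(object@snrTiers, function(t) t@tier, character(1))
  if (!identical(unname(tiers), c("low", "mid", "high", "clean")))
    return("snrTiers must be ordered low, mid, high, clean")
  v <- vapply(object@snrTiers[1:3], function(t) t@value, numeric(1))
  if (!(v[1] < v[2] && v[2] < v[3]))
    return("tier SNR values must satisfy low < mid < high")
  TRUE
})

#' BlockSpec: architecture of one autoencoder block
#'
#' The encoder consists of `encoderModules` modules, each of
#' `convsPerModule` 3x3 convolutions followed by a 2x2 max pooling and a
#' dropout layer; the decoder mirrors it with `encoderModules`
#' upsampling-deconvolutions (2x nearest-neighbour upsampling followed by a
#' convolution) each followed by dropout, and a final convolution collapsing
#' the feature channels into one output channel.
#'
#' @slot channels integer; feature maps per convolution layer (default 32).
#' @slot encoderModules integer; encoder module count (default 3).
#' @slot convsPerModule integer; convolutions per encoder module (default 2).
#' @slot kernelSide odd integer; convolution kernel side (default 3).
#' @slot poolFactor integer; pooling factor (2 is the supported value).
#' @slot dropoutRate numeric in `[0, 1)`; dropout rate (default 0.5),
#'   active during training only.
#' @slot activation character; elementwise nonlinearity (`"relu"`).
#' @seealso [blockSpec()], [buildBlock()]
#' @export
setClass("BlockSpec",
  representation(channels = "integer", encoderModules = "integer",
                 convsPerModule = "integer", kernelSide = "integer",
                 poolFactor = "integer", dropoutRate = "numeric",
                 activation = "character"))

setValidity("BlockSpec", function(object) {
  if (object@channels < 1L) return("channels must be positive")
  if (object@encoderModules < 1L) return("encoderModules must be positive")
  if (object@convsPerModule < 1L) return("convsPerModule must be positive")
  if (object@kernelSide %% 2L != 1L) return("kernelSide must be odd")
  if (object@poolFactor != 2L) return("only poolFactor = 2 is supported")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must be in [0, 1)")
  if (!object@activation %in% "relu")
    return("only the 'relu' activation is supported")
  TRUE
})

#' @param channels,encoderModules,convsPerModule,kernelSide,poolFactor,dropoutRate,activation
#'   see the class slots.
#' @return A [BlockSpec-class].
#' @examples
#' blockSpec()                   # the canonical 32-channel block
#' blockSpec(channels = 8)       # a lighter block for quick experiments
#' @rdname BlockSpec-class
#' @export
blockSpec <- function(channels = 32L, encoderModules = 3L,
                      convsPerModule = 2L, kernelSide = 3L, poolFactor = 2L,
                      dropoutRate = 0.5, activation = "relu") {
  new("BlockSpec", channels = as.integer(channels),
      encoderModules = as.integer(encoderModules),
      convsPerModule = as.integer(convsPerModule),
      kernelSide = as.integer(kernelSide),
      poolFactor = as.integer(poolFactor),
      dropoutRate = as.numeric(dropoutRate), activation = activation)
}

#' TrainConfig: optimization settings for one training run
#'
#' @slot optimizer character; `"rmsprop"` is the supported optimizer.
#' @slot epochs integer >= 0; passes over the training stack (default 20).
#'   Zero epochs is a supported no-op, used e.g. to disable fine-tuning.
#' @slot batchSize integer; minibatch size (default 8, chosen so that a
#'   20-epoch run on a few hundred images still performs enough RMSprop
#'   updates to escape the mean-image optimum; see the methods vignette).
#' @slot learningRate positive numeric (default 3e-3).
#' @slot loss character; `"mse"` (mean-square-error) is the supported loss.
#' @slot seed integer; seeds weight initialization order, minibatch
#'   shuffling and dropout masks.
#' @seealso [trainConfig()], [trainBlock()]
#' @export
setClass("TrainConfig",
  representation(optimizer = "character", epochs = "integer",
                 batchSize = "integer", learningRate = "numeric",
                 loss = "character", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 0L) return("epochs must be >= 0")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (!identical(object@optimizer, "rmsprop"))
    return("only the 'rmsprop' optimizer is supported")
  if (!identical(object@loss, "mse"))
    return("only the 'mse' loss is supported")
  TRUE
})

#' @param optimizer,epochs,batchSize,learningRate,loss,seed see the class slots.
#' @return A [TrainConfig-class].
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(epochs = 20L, batchSize = 8L, learningRate = 3e-3,
                        optimizer = "rmsprop", loss = "mse", seed = 0L) {
  new("TrainConfig", optimizer = optimizer, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), loss = loss,
      seed = as.integer(seed))
}

#' TrainedBlock: one convolutional encoder--decoder with its parameters
#'
#' Applying a block to an `(H, W)` image returns an `(H, W)` image: the
#' architecture is shape-preserving end to end for sides divisible by
#' `poolFactor ^ encoderModules`.
#'
#' @slot spec the [BlockSpec-class] the parameters conform to.
#' @slot params list of per-layer parameters (`W`: kernel matrix of size
#'   `(cin * k^2, cout)`; `b`: bias of length `cout`).
#' @slot lossHistory numeric; per-epoch training losses accumulated over
#'   all training calls applied to this block.
#' @seealso [buildBlock()], [trainBlock()], [applyBlock()]
#' @export
setClass("TrainedBlock",
  representation(spec = "BlockSpec", params = "list",
                 lossHistory = "numeric"))

setValidity("TrainedBlock", function(object) {
  k <- object@spec@kernelSide
  expected <- .convLayerChannels(object@spec)
  if (length(object@params) != nrow(expected))
    return("parameter list does not match the architecture")
  for (i in seq_along(object@params)) {
    w <- object@params[[i]]$W
    if (!identical(dim(w), c(expected[i, 1] * k * k, expected[i, 2])))
      return(sprintf("layer %d weight matrix has the wrong shape", i))
    if (length(object@params[[i]]$b) != expected[i, 2])
      return(sprintf("layer %d bias has the wrong length", i))
  }
  TRUE
})

#' NeighborConfig: neighbourhood definition for pseudo-supervision targets
#'
#' @slot k integer neighbourhood size (default 30, the canonical value).
#' @slot metric `"euclidean"` (raw pixel vectors) or `"correlation"`
#'   (one minus Pearson correlation).
#' @slot includeSelf logical; whether an image belongs to its own
#'   neighbourhood (default `TRUE`).
#' @seealso [neighborConfig()], [nearestNeighbors()], [meanTargets()]
#' @export
setClass("NeighborConfig",
  representation(k = "integer", metric = "character",
                 includeSelf = "logical"))

setValidity("NeighborConfig", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (!object@metric %in% c("euclidean", "correlation"))
    return("metric must be 'euclidean' or 'correlation'")
  TRUE
})

#' @param k,metric,includeSelf see the class slots.
#' @return A [NeighborConfig-class].
#' @rdname NeighborConfig-class
#' @export
neighborConfig <- function(k = 30L, metric = "euclidean",
                           includeSelf = TRUE) {
  new("NeighborConfig", k = as.integer(k), metric = metric,
      includeSelf = includeSelf)
}

#' NeighborGraph: the k nearest neighbours of every image in a stack
#'
#' @slot indices integer `(n, k)` matrix; row i lists image i's neighbour
#'   indices in order of non-decreasing distance (ties broken by lower
#'   index).
#' @slot distances numeric `(n, k)` matrix parallel to `indices`.
#' @seealso [nearestNeighbors()]
#' @export
setClass("NeighborGraph",
  representation(indices = "matrix", distances = "matrix"))

setValidity("NeighborGraph", function(object) {
  if (!identical(dim(object@indices), dim(object@distances)))
    return("indices and distances must have identical dimensions")
  if (any(apply(object@distances, 1L, is.unsorted)))
    return("distances must be non-decreasing within each row")
  TRUE
})

#' CascadeModel: the ordered triple of denoising blocks
#'
#' Realizes the progressive denoiser f = f3 o f2 o f1 followed by optional
#' histogram-equalization enhancement.
#'
#' @slot blocks list of three [TrainedBlock-class] objects sharing one
#'   [BlockSpec-class].
#' @slot neighborCfg the [NeighborConfig-class] used to build fine-tuning
#'   targets.
#' @slot enhance logical; apply histogram equalization to the final output
#'   (default `TRUE`).
#' @slot targetMode `"block1_fixed"` (the default: blocks 2 and 3 reuse
#'   block 1's neighbourhood-mean target stack, so every block refines
#'   toward the same clean-approximating targets) or `"per_block"` (each
#'   block's target is the neighbourhood mean of its own pre-trained
#'   outputs, which can chase the block's own distortion on
#'   distribution-shifted inputs).
#' @slot pretrained logical; set by [pretrainCascade()].
#' @seealso [pretrainCascade()], [finetuneCascade()], [denoise()]
#' @export
setClass("CascadeModel",
  representation(blocks = "list", neighborCfg = "NeighborConfig",
                 enhance = "logical", targetMode = "character",
                 pretrained = "logical"))

setValidity("CascadeModel", function(object) {
  if (!length(object@blocks))
    return("a cascade needs at least one block")
  if (!all(vapply(object@blocks, is, logical(1), "TrainedBlock")))
    return("blocks must be TrainedBlock objects")
  specs <- lapply(object@blocks, slot, "spec")
  for (s in specs[-1])
    if (!identical(s, specs[[1]]))
      return("all blocks must share one BlockSpec")
  if (!object@targetMode %in% c("per_block", "block1_fixed"))
    return("targetMode must be 'per_block' or 'block1_fixed'")
  TRUE
})

#' CascadeRunRecord: bookkeeping of one fine-tune-and-denoise run
#'
#' @slot stacks named list of [ImageStack-class]: the test input `X1`, the
#'   per-stage outputs `X2` (after block 1), `X3` (after block 2), `X4`
#'   (after block 3), and `final` (after enhancement, if enabled).
#' @slot lossHistories list of per-block fine-tuning loss vectors.
#' @slot seeds integer vector of the derived per-block seeds.
#' @export
setClass("CascadeRunRecord",
  representation(stacks = "list", lossHistories = "list",
                 seeds = "integer"))

#' PsnrReport: peak signal-to-noise ratios of a stack against a reference
#'
#' @slot perImageDb numeric vector of per-image PSNRs in dB; exact matches
#'   are capped at `ceilingDb`.
#' @slot meanDb arithmetic mean of the per-image values.
#' @slot maxVal the peak value used.
#' @slot ceilingDb the cap substituted for infinite PSNRs (default 100 dB).
#' @seealso [psnr()]
#' @export
setClass("PsnrReport",
  representation(perImageDb = "numeric", meanDb = "numeric",
                 maxVal = "numeric", ceilingDb = "numeric"))

#' ClusterAssignment: a hard partition of an image stack
#'
#' @slot labels integer vector of cluster indices in `1..K`.
#' @slot K integer number of clusters.
#' @slot method `"kmeans"` or `"hierarchical"`.
#' @slot seed integer seed used for the k-means initialization.
#' @seealso [clusterStack()]
#' @export
setClass("ClusterAssignment",
  representation(labels = "integer", K = "integer", method = "character",
                 seed = "integer"))

setValidity("ClusterAssignment", function(object) {
  if (object@K < 2L) return("K must be >= 2")
  if (any(object@labels < 1L | object@labels > object@K))
    return("cluster labels must lie in 1..K")
  TRUE
})

#' ClusteringReport: matched-class precision, recall and F1
#'
#' @slot mapping integer vector; `mapping[c]` is the true class assigned to
#'   cluster `c` by the optimal one-to-one matching.
#' @slot perClass data.frame with one row per true class: `class`,
#'   `precision`, `recall`, `f1`.
#' @slot macroPrecision,macroRecall,macroF1 unweighted means over classes.
#' @seealso [matchClusters()], [scoreClustering()]
#' @export
setClass("ClusteringReport",
  representation(mapping = "integer", perClass = "data.frame",
                 macroPrecision = "numeric", macroRecall = "numeric",
                 macroF1 = "numeric"))
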