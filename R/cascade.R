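## The cascade: tiered pre-training, sequential pseudo-supervised
## fine-tuning, and end-to-end denoising.

#' Pre-train the three cascade blocks on tiered simulated data
#'
#' Block j learns the mapping from tier j to tier j + 1: low SNR to mid,
#' mid to high, high to clean.  The four stacks must be index-aligned
#' (image i shares one clean source across tiers), as produced by
#' [buildDatasets()].  The blocks are independent and trained separately.
#'
#' @param tiers list of four index-aligned [ImageStack-class] objects,
#'   ordered low, mid, high, clean.
#' @param spec the shared [BlockSpec-class].
#' @param cfg the [TrainConfig-class]; each block's initialization and
#'   training seeds are derived from `cfg@seed` via [deriveSeed()].
#' @param neighborCfg the [NeighborConfig-class] stored in the model for
#'   later fine-tuning.
#' @param enhance logical; apply histogram equalization in [denoise()].
#' @param targetMode fine-tuning target mode, see [CascadeModel-class].
#' @param nBlocks number of blocks; the canonical cascade has 3.
#' @return A pre-trained [CascadeModel-class].
#' @export
pretrainCascade <- function(tiers, spec = blockSpec(), cfg = trainConfig(),
                            neighborCfg = neighborConfig(),
                            enhance = TRUE, targetMode = "block1_fixed",
                            nBlocks = 3L) {
  nBlocks <- as.integer(nBlocks)
  if (length(tiers) != nBlocks + 1L)
    stop(sprintf("need %d index-aligned tiers for %d blocks",
                 nBlocks + 1L, nBlocks))
  ns <- vapply(tiers, nImages, integer(1))
  if (length(unique(ns)) != 1L)
    stop("tiers are misaligned: image counts differ")
  dims <- lapply(tiers, imageDim)
  for (d in dims[-1])
    if (!identical(d, dims[[1]])) stop("tiers are misaligned: image sizes differ")
  blocks <- vector("list", nBlocks)
  for (j in seq_len(nBlocks)) {
    b <- buildBlock(spec, deriveSeed(cfg@seed, paste0("init_block", j)))
    cfgj <- cfg
    cfgj@seed <- deriveSeed(cfg@seed, paste0("pretrain_block", j))
    blocks[[j]] <- trainBlock(b, tiers[[j]], tiers[[j + 1L]], cfgj)
  }
  new("CascadeModel", blocks = blocks, neighborCfg = neighborCfg,
      enhance = enhance, targetMode = targetMode, pretrained = TRUE)
}

#' Fine-tune the cascade on a target stack with neighbourhood-mean targets
#'
#' Sequential pseudo-supervised adaptation: block 1 is fine-tuned with the
#' test stack as input and the neighbourhood means of its own pre-trained
#' outputs as targets; its output feeds block 2, and so on.  Each
#' fine-tuned block is initialized from its pre-trained parameters.  In
#' `"per_block"` mode each block's targets are the neighbourhood means of
#' that block's pre-trained output on its own input; in `"block1_fixed"`
#' mode blocks 2 and 3 reuse block 1's target stack.
#'
#' @param model a pre-trained [CascadeModel-class].
#' @param test the target [ImageStack-class] (no clean targets needed).
#' @param cfg [TrainConfig-class] for fine-tuning; per-block seeds derive
#'   from `cfg@seed`.  `epochs = 0` leaves the model unchanged.
#' @param targetMode overrides the model's target mode if given.
#' @param neighborOn whether each block's neighbourhood graph is computed
#'   on the block's pre-trained `"output"` (default; the partly denoised
#'   images give more reliable similarities) or on its raw `"input"`
#'   stack.  The targets are neighbourhood means of the block output
#'   either way.
#' @return A list with `model` (the fine-tuned [CascadeModel-class]) and
#'   `record` (a [CascadeRunRecord-class] holding the intermediate stacks
#'   `X1`..`X4` and the enhanced `final`).
#' @export
finetuneCascade <- function(model, test, cfg = trainConfig(),
                            targetMode = NULL,
                            neighborOn = c("output", "input")) {
  neighborOn <- match.arg(neighborOn)
  stopifnot(is(model, "CascadeModel"), is(test, "ImageStack"))
  if (!model@pretrained)
    stop("the cascade must be pre-trained before fine-tuning")
  mode <- if (is.null(targetMode)) model@targetMode else targetMode
  if (!mode %in% c("per_block", "block1_fixed"))
    stop("targetMode must be 'per_block' or 'block1_fixed'")

  nb <- length(model@blocks)
  X <- test
  stacks <- vector("list", nb + 2L)
  names(stacks) <- c(paste0("X", seq_len(nb + 1L)), "final")
  stacks[[1L]] <- X
  lossHistories <- vector("list", nb)
  seeds <- integer(nb)
  block1Targets <- NULL
  for (j in seq_len(nb)) {
    preOut <- applyBlock(model@blocks[[j]], X)
    if (mode == "per_block" || j == 1L) {
      graphOn <- if (neighborOn == "output") preOut else X
      D <- pairwiseDistances(graphOn, model@neighborCfg@metric)
      g <- nearestNeighbors(D, model@neighborCfg)
      targets <- meanTargets(preOut, g)
      if (j == 1L) block1Targets <- targets
    } else {
      targets <- block1Targets
    }
    cfgj <- cfg
    cfgj@seed <- deriveSeed(cfg@seed, paste0("finetune_block", j))
    seeds[j] <- cfgj@seed
    nOld <- length(model@blocks[[j]]@lossHistory)
    model@blocks[[j]] <- trainBlock(model@blocks[[j]], X, targets, cfgj)
    lossHistories[[j]] <-
      model@blocks[[j]]@lossHistory[seq_len(cfg@epochs) + nOld]
    X <- applyBlock(model@blocks[[j]], X)
    stacks[[j + 1L]] <- X
  }
  stacks[["final"]] <- if (model@enhance) histogramEqualize(X) else X
  record <- new("CascadeRunRecord", stacks = stacks,
                lossHistories = lossHistories, seeds = seeds)
  list(model = model, record = record)
}

#' Denoise a stack with the cascade
#'
#' Sequential application of the blocks, then histogram equalization per
#' image if the model's `enhance` flag is set.  Deterministic.
#'
#' @param model a pre-trained (optionally fine-tuned) [CascadeModel-class].
#' @param images the [ImageStack-class] to denoise.
#' @param enhance overrides the model's enhance flag if given.
#' @return The denoised [ImageStack-class].
#' @export
denoise <- function(model, images, enhance = NULL) {
  stopifnot(is(model, "CascadeModel"))
  if (!model@pretrained)
    stop("the cascade must be pre-trained before denoising")
  doEnhance <- if (is.null(enhance)) model@enhance else enhance
  X <- images
  for (b in model@blocks) X <- applyBlock(b, X)
  if (doEnhance) X <- histogramEqualize(X) else X
}
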