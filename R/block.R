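## One convolutional denoising autoencoder block: build, train, apply.

# (cin, cout) per convolution layer implied by a BlockSpec, in order.
.convLayerChannels <- function(spec) {
  C <- spec@channels
  enc <- do.call(rbind, lapply(seq_len(spec@encoderModules), function(m) {
    cins <- rep(C, spec@convsPerModule)
    if (m == 1L) cins[1] <- 1L
    cbind(cins, rep(C, spec@convsPerModule))
  }))
  dec <- cbind(rep(C, spec@encoderModules), rep(C, spec@encoderModules))
  out <- rbind(enc, dec, c(C, 1L))
  dimnames(out) <- NULL
  out
}

#' Number of trainable parameters of a block architecture
#'
#' Closed form: the sum over convolution layers of
#' `cout * (cin * kernelSide^2 + 1)`.
#'
#' @param spec a [BlockSpec-class] or [TrainedBlock-class].
#' @return Integer parameter count.
#' @examples
#' nParams(blockSpec())   # 74593 for the canonical 32-channel block
#' @export
nParams <- function(spec) {
  if (is(spec, "TrainedBlock")) spec <- spec@spec
  stopifnot(is(spec, "BlockSpec"))
  as.integer(.cae_param_count(spec@channels, spec@encoderModules,
                              spec@convsPerModule, spec@kernelSide))
}

#' Build an (untrained) autoencoder block
#'
#' Parameters are initialized deterministically from the seed with a
#' uniform fan-in scheme (LeCun uniform); biases start at zero.
#'
#' @param spec a [BlockSpec-class].
#' @param seed integer initialization seed.
#' @return A [TrainedBlock-class] with empty loss history.
#' @examples
#' b <- buildBlock(blockSpec(channels = 4), seed = 1)
#' @export
buildBlock <- function(spec, seed = 1L) {
  stopifnot(is(spec, "BlockSpec"))
  params <- .cae_init(spec@channels, spec@encoderModules,
                      spec@convsPerModule, spec@kernelSide,
                      as.integer(seed))
  new("TrainedBlock", spec = spec, params = params,
      lossHistory = numeric(0))
}

#' Train a block on (input, target) image pairs
#'
#' Minimizes the mean-square reconstruction error between the block's
#' output on each input image and the corresponding target image, by
#' minibatch RMSprop.  Dropout is active during training only.  With
#' `cfg@epochs == 0` the block is returned unchanged.
#'
#' @param block a [TrainedBlock-class].
#' @param inputs input [ImageStack-class].
#' @param targets target [ImageStack-class]; must match `inputs` in length
#'   and image size.
#' @param cfg a [TrainConfig-class].
#' @return The trained [TrainedBlock-class]; the new per-epoch losses are
#'   appended to its `lossHistory`.
#' @examples
#' s <- imageStack(array(0.5, c(16, 16, 8)))
#' b <- buildBlock(blockSpec(channels = 2), seed = 1)
#' b <- trainBlock(b, s, s, trainConfig(epochs = 2, seed = 1))
#' @export
trainBlock <- function(block, inputs, targets, cfg = trainConfig()) {
  stopifnot(is(block, "TrainedBlock"), is(cfg, "TrainConfig"))
  xin <- asPixelArray(inputs)
  tgt <- asPixelArray(targets)
  if (!identical(dim(xin), dim(tgt)))
    stop("inputs and targets must have identical length and image size")
  if (cfg@epochs == 0L) return(block)
  s <- block@spec
  res <- .cae_train(block@params, xin, tgt, s@channels, s@encoderModules,
                    s@convsPerModule, s@kernelSide, s@poolFactor,
                    cfg@epochs, cfg@batchSize, cfg@learningRate,
                    s@dropoutRate, cfg@seed)
  block@params <- res$params
  block@lossHistory <- c(block@lossHistory, res$loss)
  block
}

#' Apply a block to an image stack
#'
#' Deterministic inference (dropout disabled).  Stack order, labels and
#' clean references are preserved; the SNR tag is dropped because the
#' output noise level is no longer the calibrated one.
#'
#' @param block a [TrainedBlock-class].
#' @param images an [ImageStack-class] whose sides are divisible by
#'   `poolFactor ^ encoderModules`.
#' @return The denoised [ImageStack-class].
#' @export
applyBlock <- function(block, images) {
  stopifnot(is(block, "TrainedBlock"))
  px <- asPixelArray(images)
  s <- block@spec
  out <- .cae_apply(block@params, px, s@channels, s@encoderModules,
                    s@convsPerModule, s@kernelSide, s@poolFactor)
  new("ImageStack", pixels = out,
      labels = if (is(images, "ImageStack")) images@labels else integer(0),
      snrValue = NA_real_, snrTier = NA_character_,
      cleanRef = if (is(images, "ImageStack")) images@cleanRef else NULL)
}

#' Serialize a trained block to a weights file
#'
#' The file embeds the [BlockSpec-class]; [readBlock()] restores a block
#' whose inference is bit-identical to the saved one.
#'
#' @param block a [TrainedBlock-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeBlock <- function(block, path) {
  stopifnot(is(block, "TrainedBlock"))
  saveRDS(block, path)
  invisible(path)
}

#' @rdname writeBlock
#' @export
readBlock <- function(path) {
  block <- readRDS(path)
  if (!is(block, "TrainedBlock"))
    stop("'", path, "' does not contain a TrainedBlock")
  validObject(block)
  block
}
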