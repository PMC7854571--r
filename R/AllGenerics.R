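## Generics and simple accessor / show methods.

#' Number of images in a stack
#' @param x an [ImageStack-class].
#' @return integer count.
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @rdname nImages
#' @export
setMethod("nImages", "ImageStack", function(x) dim(x@pixels)[3L])

#' Image dimensions of a stack
#' @param x an [ImageStack-class].
#' @return integer `c(H, W)`.
#' @export
setGeneric("imageDim", function(x) standardGeneric("imageDim"))

#' @rdname imageDim
#' @export
setMethod("imageDim", "ImageStack", function(x) dim(x@pixels)[1:2])

#' Pixel array of a stack
#' @param x an [ImageStack-class].
#' @return the `(H, W, N)` numeric array.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "ImageStack", function(x) x@pixels)

#' Orientation class labels of a stack
#' @param object an [ImageStack-class].
#' @param ... ignored.
#' @param value integer vector of labels (or `NULL` to drop them).
#' @return integer vector (`integer(0)` if the stack is unlabeled).
#' @export
setMethod("labels", "ImageStack", function(object, ...) object@labels)

#' @rdname labels-ImageStack-method
#' @export
setGeneric("labels<-", function(object, value) standardGeneric("labels<-"))

#' @rdname labels-ImageStack-method
#' @export
setMethod("labels<-", "ImageStack", function(object, value) {
  object@labels <- if (is.null(value)) integer(0) else as.integer(value)
  validObject(object)
  object
})

#' Clean reference stack
#' @param x an [ImageStack-class].
#' @param value an `(H, W, N)` array or `NULL`.
#' @return the clean `(H, W, N)` array, or `NULL`.
#' @export
setGeneric("cleanRef", function(x) standardGeneric("cleanRef"))

#' @rdname cleanRef
#' @export
setMethod("cleanRef", "ImageStack", function(x) x@cleanRef)

#' @rdname cleanRef
#' @export
setGeneric("cleanRef<-", function(x, value) standardGeneric("cleanRef<-"))

#' @rdname cleanRef
#' @export
setMethod("cleanRef<-", "ImageStack", function(x, value) {
  x@cleanRef <- value
  validObject(x)
  x
})

#' SNR tag of a stack
#' @param x an [ImageStack-class].
#' @return named list with `value` and `tier` (`NA` when untagged).
#' @export
setGeneric("snrTag", function(x) standardGeneric("snrTag"))

#' @rdname snrTag
#' @export
setMethod("snrTag", "ImageStack", function(x)
  list(value = x@snrValue, tier = x@snrTier))

#' Subset an image stack
#'
#' Selects images (third-axis slices); labels and clean references are
#' subset in parallel.
#'
#' @param x an [ImageStack-class].
#' @param i integer or logical index vector over images.
#' @param j,...,drop ignored.
#' @return An [ImageStack-class].
#' @export
setMethod("[", "ImageStack", function(x, i, j, ..., drop = FALSE) {
  new("ImageStack",
      pixels = x@pixels[, , i, drop = FALSE],
      labels = if (length(x@labels)) x@labels[i] else integer(0),
      snrValue = x@snrValue, snrTier = x@snrTier,
      cleanRef = if (!is.null(x@cleanRef)) x@cleanRef[, , i, drop = FALSE]
                 else NULL)
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageStack: %d image(s) of %d x %d\n", d[3], d[1], d[2]))
  if (!is.na(object@snrTier))
    cat(sprintf("  SNR tier: %s (%.3g)\n", object@snrTier, object@snrValue))
  if (length(object@labels))
    cat(sprintf("  labels: %d class(es)\n", length(unique(object@labels))))
  if (!is.null(object@cleanRef)) cat("  clean references: yes\n")
})

setMethod("show", "PhantomVolume", function(object) {
  cat(sprintf("PhantomVolume: %d^3 voxels, %d component(s), max density %.3g\n",
              object@side, length(object@components), max(object@grid)))
})

setMethod("show", "TrainedBlock", function(object) {
  s <- object@spec
  cat(sprintf(
    "TrainedBlock: %d channels, %d encoder modules (%d convs each), kernel %d\n",
    s@channels, s@encoderModules, s@convsPerModule, s@kernelSide))
  cat(sprintf("  parameters: %d; trained epochs: %d\n",
              nParams(s), length(object@lossHistory)))
})

setMethod("show", "CascadeModel", function(object) {
  cat(sprintf("CascadeModel: %d block(s), %s\n", length(object@blocks),
              if (object@pretrained) "pre-trained" else "untrained"))
  cat(sprintf("  neighbourhood k = %d (%s), enhance = %s, targets = %s\n",
              object@neighborCfg@k, object@neighborCfg@metric,
              object@enhance, object@targetMode))
})

setMethod("show", "PsnrReport", function(object) {
  cat(sprintf("PsnrReport: mean %.3f dB over %d image(s) (peak %.3g)\n",
              object@meanDb, length(object@perImageDb), object@maxVal))
})

setMethod("show", "ClusteringReport", function(object) {
  cat(sprintf("ClusteringReport: macro P/R/F1 = %.3f / %.3f / %.3f\n",
              object@macroPrecision, object@macroRecall, object@macroF1))
  print(object@perClass, row.names = FALSE)
})
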