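## Histogram-equalization enhancement and image-quality metrics.

# Core CDF remap for a single matrix.
.equalizeMatrix <- function(x, nBins) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(x)  # degenerate CDF: constant image
  b <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * nBins), nBins - 1L)
  counts <- tabulate(b + 1L, nbins = nBins)
  cdf <- cumsum(counts) / length(x)
  matrix(cdf[b + 1L], nrow(x), ncol(x))
}

#' Histogram equalization
#'
#' Rank-preserving monotone remap of pixel intensities through the
#' empirical CDF, computed per image over `nBins` equal-width bins spanning
#' the image's own range.  The output lies in `(0, 1]`; a constant image is
#' returned unchanged.  Denoised cryo-EM images concentrate their gray
#' values in a narrow range, and equalization spreads them over the full
#' range, enhancing structural contrast.
#'
#' @param x a numeric matrix (one image) or an [ImageStack-class].
#' @param nBins number of histogram bins (default 256).
#' @return An object of the same kind as `x`.
#' @examples
#' img <- matrix(c(0.1, 0.1, 0.2, 0.9), 2)
#' histogramEqualize(img, nBins = 4)
#' @export
histogramEqualize <- function(x, nBins = 256L) {
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be at least 2")
  if (is.matrix(x)) {
    if (!all(is.finite(x))) stop("pixel values must be finite")
    return(.equalizeMatrix(x, nBins))
  }
  stopifnot(is(x, "ImageStack"))
  if (!all(is.finite(x@pixels))) stop("pixel values must be finite")
  out <- x@pixels
  for (i in seq_len(dim(out)[3]))
    out[, , i] <- .equalizeMatrix(out[, , i], nBins)
  x@pixels <- out
  x@snrValue <- NA_real_
  x@snrTier <- NA_character_
  x
}

#' Peak signal-to-noise ratio
#'
#' Per image, `10 * log10(maxVal^2 / MSE)` with the mean-square error taken
#' over all pixels.  Identical images (zero MSE) are reported at the
#' `ceilingDb` cap so the mean stays finite.  By convention the peak is 1
#' for stacks normalized to `[0, 1]`.
#'
#' @param reference reference image/stack ([ImageStack-class], matrix or
#'   `(H, W, N)` array).
#' @param test test image/stack of identical dimensions.
#' @param maxVal positive peak value (default 1).
#' @param ceilingDb cap substituted for infinite PSNRs (default 100 dB).
#' @return A [PsnrReport-class].
#' @examples
#' a <- matrix(0, 8, 8); b <- matrix(0.1, 8, 8)
#' psnr(a, b)@meanDb   # exactly 20 dB
#' @export
psnr <- function(reference, test, maxVal = 1, ceilingDb = 100) {
  if (maxVal <= 0) stop("maxVal must be positive")
  ref <- asPixelArray(reference)
  tst <- asPixelArray(test)
  if (!identical(dim(ref), dim(tst)))
    stop("reference and test must have identical dimensions")
  n <- dim(ref)[3]
  per <- vapply(seq_len(n), function(i) {
    mse <- mean((ref[, , i] - tst[, , i])^2)
    if (mse == 0) ceilingDb
    else min(10 * log10(maxVal^2 / mse), ceilingDb)
  }, numeric(1))
  new("PsnrReport", perImageDb = per, meanDb = mean(per),
      maxVal = as.numeric(maxVal), ceilingDb = as.numeric(ceilingDb))
}

#' Mean PSNR of a stack against its clean references
#'
#' Convenience wrapper: PSNR of `stack` (or any substitute pixel array)
#' against `cleanRef(stack)`.
#'
#' @param stack an [ImageStack-class] carrying clean references.
#' @param pixels optional replacement pixel array/stack scored against the
#'   same references (e.g. a denoised version of `stack`).
#' @param ... passed to [psnr()].
#' @return A [PsnrReport-class].
#' @export
psnrVsClean <- function(stack, pixels = NULL, ...) {
  stopifnot(is(stack, "ImageStack"))
  if (is.null(stack@cleanRef)) stop("stack carries no clean references")
  tst <- if (is.null(pixels)) stack@pixels else asPixelArray(pixels)
  psnr(stack@cleanRef, tst, ...)
}

#' Write per-image PSNRs as a flat CSV table
#'
#' @param reports named list of [PsnrReport-class] objects (name = stage).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePsnrTable <- function(reports, path) {
  rows <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(image = seq_along(r@perImageDb), stage = nm,
               psnr_db = r@perImageDb)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
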