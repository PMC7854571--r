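## Stack I/O: MRC (mode 2, float32), RDS array container, PNG export,
## YAML manifests.

#' Write an image stack as an MRC file (mode 2, 32-bit float)
#'
#' Minimal MRC2014 writer: little-endian, `nx = H`, `ny = W`, `nz = N`,
#' no extended header.  MRC stores 32-bit floats, so values are quantized
#' to single precision; round-trips are lossless for data already at
#' float32 precision (see [toFloat32()]).  Labels and SNR metadata are not
#' representable in MRC; use [writeStack()] for a lossless container.
#'
#' @param stack an [ImageStack-class] or `(H, W, N)` array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMRC <- function(stack, path) {
  px <- asPixelArray(stack)
  d <- dim(px)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                               endian = "little")
  wInt(d)                    # nx, ny, nz
  wInt(2L)                   # mode 2: float32
  wInt(c(0L, 0L, 0L))        # nxstart
  wInt(d)                    # mx, my, mz
  wFlt(as.numeric(d))        # cella (1 A / pixel)
  wFlt(c(90, 90, 90))        # cellb
  wInt(c(1L, 2L, 3L))        # mapc, mapr, maps
  wFlt(c(min(px), max(px), mean(px)))  # dmin, dmax, dmean
  wInt(c(0L, 0L))            # ispg, nsymbt
  wInt(rep(0L, 25L))         # extra
  wFlt(c(0, 0, 0))           # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wFlt(sqrt(mean((px - mean(px))^2)))  # rms
  wInt(0L)                   # nlabl
  writeBin(raw(800L), con)   # label block
  wFlt(as.numeric(px))
  invisible(path)
}

#' Read an MRC file written in mode 2
#'
#' @param path MRC file path.
#' @return An [ImageStack-class] (unlabeled, untagged).
#' @rdname writeMRC
#' @export
readMRC <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rInt <- function(n) readBin(con, "integer", n, size = 4L,
                              endian = "little")
  d <- rInt(3L)
  mode <- rInt(1L)
  if (mode != 2L)
    stop("unsupported MRC mode ", mode, " (only mode 2, float32, is read)")
  rInt(19L)                              # through dmean
  nsymbt <- rInt(2L)[2]
  seek(con, 1024L + nsymbt)
  n <- prod(d)
  px <- readBin(con, "numeric", n, size = 4L, endian = "little")
  if (length(px) != n) stop("truncated MRC file: ", path)
  imageStack(array(px, d))
}

#' Quantize values to 32-bit float precision
#'
#' @param x numeric vector/array.
#' @return `x` rounded to the nearest representable float32 value.
#' @export
toFloat32 <- function(x) {
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
                 length(x), size = 4L)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Lossless array-container I/O for image stacks
#'
#' Serializes the full [ImageStack-class] -- double-precision pixels,
#' labels, SNR tag and clean references -- to an RDS file.
#'
#' @param stack an [ImageStack-class].
#' @param path file path.
#' @return `path` invisibly; `readStack()` returns the stack.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  saveRDS(stack, path)
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  s <- readRDS(path)
  if (!is(s, "ImageStack")) stop("'", path, "' does not contain an ImageStack")
  validObject(s)
  s
}

#' Export a stack as 8-bit PNG images
#'
#' Pixel values are clipped to `[0, 1]` on export; PNGs are for viewing
#' only, never for metric computation.
#'
#' @param stack an [ImageStack-class] or array.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
exportPNG <- function(stack, dir, prefix = "img") {
  px <- asPixelArray(stack)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(dim(px)[3])
  for (i in seq_len(dim(px)[3])) {
    paths[i] <- file.path(dir, sprintf("%s_%04d.png", prefix, i))
    png::writePNG(pmin(pmax(px[, , i], 0), 1), paths[i])
  }
  invisible(paths)
}

#' Write / read a simulation manifest
#'
#' Records the plan parameters and seeds of a simulated dataset as YAML so
#' a run can be reproduced from its output directory alone.
#'
#' @param plan a [SimulationPlan-class].
#' @param path YAML file path.
#' @param neighborCfg optional [NeighborConfig-class] whose neighbourhood
#'   size is recorded alongside the plan.
#' @return `path` invisibly; `readManifest()` returns the parameter list.
#' @export
writeManifest <- function(plan, path, neighborCfg = NULL) {
  stopifnot(is(plan, "SimulationPlan"))
  out <- list(
    image_side = plan@imageSide,
    n_per_class = plan@nPerClass,
    n_orientations = nrow(plan@orientations),
    orientations = apply(plan@orientations, 1L, paste, collapse = ","),
    snr = list(low = plan@snrTiers$low@value, mid = plan@snrTiers$mid@value,
               high = plan@snrTiers$high@value),
    seed = plan@seed,
    phantom_components = length(plan@phantom@components))
  if (!is.null(neighborCfg))
    out$k_neighbors <- neighborCfg@k
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) yaml::read_yaml(path)
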