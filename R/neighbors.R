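## Neighbourhood-mean pseudo-supervision targets.

#' Pairwise distances between the images of a stack
#'
#' Euclidean distance on raw (flattened, unnormalized) pixel vectors, or
#' correlation distance `1 - r` (Pearson).  The result is a symmetric
#' `n x n` matrix with zero diagonal.
#'
#' @param stack an [ImageStack-class] (or `(H, W, N)` array) with at least
#'   two images.
#' @param metric `"euclidean"` or `"correlation"`.
#' @return A symmetric numeric distance matrix.
#' @examples
#' s <- imageStack(array(runif(8 * 8 * 4), c(8, 8, 4)))
#' d <- pairwiseDistances(s)
#' @export
pairwiseDistances <- function(stack, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  px <- asPixelArray(stack)
  n <- dim(px)[3]
  if (n < 2L) stop("at least two images are required")
  X <- matrix(px, ncol = n)  # pixels x images
  if (metric == "euclidean") {
    D <- as.matrix(dist(t(X)))
    dimnames(D) <- NULL
    D
  } else {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0))
      stop("correlation distance is undefined for constant images (image ",
           paste(which(sds == 0), collapse = ", "), ")")
    D <- 1 - cor(X)
    diag(D) <- 0
    dimnames(D) <- NULL
    D
  }
}

#' Select the k nearest neighbours of every image
#'
#' For each image, the `k` smallest-distance indices (ties broken by lower
#' index).  With `includeSelf = TRUE` the image itself (distance zero) is
#' always its first neighbour.
#'
#' @param dist symmetric `n x n` distance matrix from [pairwiseDistances()].
#' @param cfg a [NeighborConfig-class].
#' @return A [NeighborGraph-class].
#' @examples
#' s <- imageStack(array(runif(8 * 8 * 6), c(8, 8, 6)))
#' g <- nearestNeighbors(pairwiseDistances(s), neighborConfig(k = 3))
#' @export
nearestNeighbors <- function(dist, cfg = neighborConfig()) {
  stopifnot(is(cfg, "NeighborConfig"))
  n <- nrow(dist)
  kmax <- if (cfg@includeSelf) n else n - 1L
  if (cfg@k > kmax)
    stop(sprintf("k = %d out of range (at most %d for %d images)",
                 cfg@k, kmax, n))
  idx <- matrix(0L, n, cfg@k)
  dst <- matrix(0, n, cfg@k)
  for (i in seq_len(n)) {
    ord <- order(dist[i, ])  # stable: ties broken by lower index
    if (!cfg@includeSelf) ord <- ord[ord != i]
    sel <- ord[seq_len(cfg@k)]
    idx[i, ] <- sel
    dst[i, ] <- dist[i, sel]
  }
  new("NeighborGraph", indices = idx, distances = dst)
}

#' Neighbourhood-mean target images
#'
#' Image `i` of the result is the arithmetic pixel mean of the stack
#' images at its neighbour indices: the pseudo-supervision target used in
#' fine-tuning.  Averaging k images with independent noise reduces the
#' noise variance by about 1/k while preserving the shared signal, so the
#' mean image stands in for the unavailable clean target.
#'
#' @param stack the [ImageStack-class] the graph was built on.
#' @param graph a [NeighborGraph-class].
#' @return An [ImageStack-class] of target images; labels pass through.
#' @export
meanTargets <- function(stack, graph) {
  stopifnot(is(graph, "NeighborGraph"))
  px <- asPixelArray(stack)
  n <- dim(px)[3]
  if (nrow(graph@indices) != n)
    stop("graph was not built on this stack")
  out <- array(0, dim(px))
  for (i in seq_len(n)) {
    sel <- graph@indices[i, ]
    out[, , i] <- rowMeans(array(px[, , sel], c(dim(px)[1:2], length(sel))),
                           dims = 2L)
  }
  new("ImageStack", pixels = out,
      labels = if (is(stack, "ImageStack")) stack@labels else integer(0),
      snrValue = NA_real_, snrTier = NA_character_, cleanRef = NULL)
}

#' Serialize / restore a neighbour graph
#'
#' Plain whitespace-separated text: one row per image holding the `k`
#' neighbour indices followed by the `k` distances.
#'
#' @param graph a [NeighborGraph-class].
#' @param path file path.
#' @return `path` invisibly; `readNeighborGraph()` returns the graph.
#' @export
writeNeighborGraph <- function(graph, path) {
  stopifnot(is(graph, "NeighborGraph"))
  utils::write.table(cbind(graph@indices, graph@distances), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeNeighborGraph
#' @export
readNeighborGraph <- function(path) {
  m <- as.matrix(utils::read.table(path))
  k <- ncol(m) %/% 2L
  new("NeighborGraph",
      indices = matrix(as.integer(m[, seq_len(k)]), nrow(m)),
      distances = matrix(m[, k + seq_len(k)], nrow(m)))
}
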