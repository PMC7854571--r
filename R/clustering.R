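## Orientation clustering and matched-class precision / recall / F1.

#' Cluster an image stack
#'
#' K-means on flattened pixel vectors (seeded initialization, `nstart`
#' restarts, fixed iteration cap) or agglomerative hierarchical clustering
#' (Ward linkage on Euclidean distances) cut at `K` clusters.
#'
#' @param stack an [ImageStack-class] or `(H, W, N)` array with at least
#'   `K` images.
#' @param K number of clusters (>= 2).
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param seed integer seed for the k-means initialization.
#' @param nstart k-means restarts (default 10).
#' @param iterMax k-means iteration cap (default 100).
#' @return A [ClusterAssignment-class].
#' @export
clusterStack <- function(stack, K, method = c("kmeans", "hierarchical"),
                         seed = 0L, nstart = 10L, iterMax = 100L) {
  method <- match.arg(method)
  px <- asPixelArray(stack)
  n <- dim(px)[3]
  K <- as.integer(K)
  if (K > n) stop(sprintf("K = %d exceeds the stack size %d", K, n))
  X <- t(matrix(px, ncol = n))
  key <- apply(X, 1L, paste, collapse = "\r")
  nDistinct <- length(unique(key))
  lab <- if (nDistinct < K) {
    # degenerate stack (fewer distinct images than clusters, e.g. a
    # collapsed denoiser output): each distinct image is its own
    # cluster and the remaining clusters stay empty
    match(key, unique(key))
  } else if (method == "kmeans") {
    withSeed(seed, kmeans(X, centers = K, nstart = nstart,
                          iter.max = iterMax)$cluster)
  } else {
    cutree(hclust(dist(X), method = "ward.D2"), k = K)
  }
  new("ClusterAssignment", labels = as.integer(unname(lab)), K = K,
      method = method, seed = as.integer(seed))
}

# Hungarian algorithm (Jonker-style potentials, O(n^3)) for a square cost
# matrix; returns for each row the column of the minimum-cost assignment.
solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)    # p[j]: row currently matched to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= n) minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) assign[p[j]] <- j
  assign
}

#' Match unsupervised clusters to true classes
#'
#' Finds the one-to-one cluster-to-class mapping that maximizes the total
#' number of correctly assigned images (optimal assignment on the
#' contingency table; when cluster and class counts differ the table is
#' padded with zero rows/columns and unmatched clusters map to `NA`).
#'
#' @param assign a [ClusterAssignment-class] (or integer cluster vector).
#' @param truth integer vector of true class labels, same length.
#' @return Integer vector `mapping`; `mapping[c]` is the true class
#'   assigned to cluster `c`.
#' @examples
#' truth <- c(1, 1, 1, 2, 2)
#' matchClusters(c(2L, 2L, 2L, 1L, 1L), truth)   # c(2, 1): permutation undone
#' @export
matchClusters <- function(assign, truth) {
  cl <- if (is(assign, "ClusterAssignment")) assign@labels else as.integer(assign)
  truth <- as.integer(truth)
  if (length(cl) != length(truth))
    stop("cluster and truth label counts differ")
  K <- max(cl)
  classes <- sort(unique(truth))
  C <- length(classes)
  n <- max(K, C)
  tab <- matrix(0, n, n)
  for (i in seq_along(cl))
    tab[cl[i], match(truth[i], classes)] <-
      tab[cl[i], match(truth[i], classes)] + 1
  cols <- solveAssignment(max(tab) - tab)
  mapping <- ifelse(cols[seq_len(K)] <= C, classes[cols[seq_len(K)]],
                    NA_integer_)
  as.integer(mapping)
}

#' Score a matched clustering with precision, recall and F1
#'
#' Each image's predicted class is its cluster's matched class; per true
#' class `c`, precision = TP / (TP + FP) and recall = TP / (TP + FN) over
#' image memberships, F1 is their harmonic mean (0 when both are 0, and
#' precision is 0 for a class that receives no images).  Macro averages
#' are unweighted class means.
#'
#' @param assign a [ClusterAssignment-class] (or integer cluster vector).
#' @param truth integer vector of true class labels.
#' @param mapping cluster-to-class mapping from [matchClusters()];
#'   computed if omitted.
#' @return A [ClusteringReport-class].
#' @examples
#' truth <- rep(1:2, each = 5)
#' clusters <- c(rep(1L, 5), 2L, rep(2L, 4))
#' scoreClustering(clusters, truth)
#' @export
scoreClustering <- function(assign, truth, mapping = NULL) {
  cl <- if (is(assign, "ClusterAssignment")) assign@labels else as.integer(assign)
  truth <- as.integer(truth)
  if (is.null(mapping)) mapping <- matchClusters(cl, truth)
  pred <- mapping[cl]
  classes <- sort(unique(truth))
  per <- do.call(rbind, lapply(classes, function(cc) {
    tp <- sum(!is.na(pred) & pred == cc & truth == cc)
    fp <- sum(!is.na(pred) & pred == cc & truth != cc)
    fn <- sum((is.na(pred) | pred != cc) & truth == cc)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(class = cc, precision = p, recall = r, f1 = f)
  }))
  new("ClusteringReport", mapping = as.integer(mapping), perClass = per,
      macroPrecision = mean(per$precision), macroRecall = mean(per$recall),
      macroF1 = mean(per$f1))
}

#' Write a clustering report as CSV
#'
#' One row per class plus a macro-average row, with precision, recall and
#' F1 columns.
#'
#' @param report a [ClusteringReport-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeClusteringReport <- function(report, path) {
  rows <- rbind(
    data.frame(class = as.character(report@perClass$class),
               precision = report@perClass$precision,
               recall = report@perClass$recall, f1 = report@perClass$f1),
    data.frame(class = "macro", precision = report@macroPrecision,
               recall = report@macroRecall, f1 = report@macroF1))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
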