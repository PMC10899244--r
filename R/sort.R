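# PCA waveform features and k-means unit isolation.

#' PCA waveform features
#'
#' Projects mean-centred snippets onto the top `d` principal axes
#' (default 8, the feature space in which the cluster-quality statistics
#' are computed).  The sign of each axis is fixed so that its
#' largest-magnitude loading is positive, making feature matrices
#' reproducible across runs.
#'
#' @param snippets a [SnippetArray-class] or waveform matrix.
#' @param d number of components (default 8).
#' @return n_spikes x d feature matrix with attributes `rotation` and
#'   `center`.
#' @export
pcaFeatures <- function(snippets, d = 8) {
  X <- if (is(snippets, "SnippetArray")) snippets@waveforms else snippets
  if (nrow(X) <= d)
    stop(sprintf("need more than d = %d spikes for PCA (got %d)",
                 d, nrow(X)))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  d <- min(d, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  flip <- vapply(seq_len(d), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(X, 2, pc$center) %*% rot
  colnames(scores) <- paste0("PC", seq_len(d))
  attr(scores, "rotation") <- rot
  attr(scores, "center") <- pc$center
  scores
}

#' K-means unit isolation
#'
#' Standard k-means on the feature matrix with `nRestarts` seeded random
#' initializations, keeping the restart with minimal within-cluster sum of
#' squares.  Labels are renumbered by decreasing cluster size (ties by
#' first occurrence) so the output is deterministic given
#' `(seed, nRestarts)`.
#'
#' @param features n_spikes x d feature matrix.
#' @param k number of clusters (`1 <= k <= n_spikes`).
#' @param seed RNG seed.
#' @param nRestarts random restarts.
#' @return integer vector of labels in `1..k` with attributes `k`, `seed`
#'   and `withinss` (total within-cluster sum of squares).
#' @export
kmeansCluster <- function(features, k, seed = 1, nRestarts = 10) {
  n <- nrow(features)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop(sprintf("k = %d exceeds the %d available spikes", k, n))
  labels <- if (k == 1) rep(1L, n) else withSeed(seed, {
    fit <- stats::kmeans(features, centers = k, nstart = nRestarts,
                         iter.max = 200)
    fit$cluster
  })
  # canonical renumbering: by decreasing size, ties broken by first spike
  size <- table(labels)
  firstAt <- vapply(names(size), function(l) match(as.integer(l), labels), 0L)
  ord <- order(-as.integer(size), firstAt)
  remap <- integer(k)
  remap[as.integer(names(size))[ord]] <- seq_len(k)
  out <- remap[labels]
  tot <- sum(vapply(seq_len(k), function(c) {
    m <- features[out == c, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }, 0))
  structure(as.integer(out), k = as.integer(k), seed = as.integer(seed),
            withinss = tot)
}

#' Suggest a cluster count by mean silhouette
#'
#' Utility only: evaluates k-means over `k = 2..kMax` and reports the mean
#' silhouette width of each, never auto-applied by the pipeline (the
#' cluster count is a per-channel user decision).
#'
#' @inheritParams kmeansCluster
#' @param kMax largest k to evaluate.
#' @return data.frame with columns `k`, `meanSilhouette`; the row with the
#'   best score is attached as attribute `"best"`.
#' @export
suggestK <- function(features, kMax = 6, seed = 1, nRestarts = 10) {
  kMax <- min(kMax, nrow(features) - 1)
  D <- stats::dist(features)
  res <- data.frame(k = integer(0), meanSilhouette = numeric(0))
  for (k in 2:kMax) {
    lab <- kmeansCluster(features, k, seed = seed, nRestarts = nRestarts)
    sil <- cluster::silhouette(as.integer(lab), D)
    res <- rbind(res, data.frame(k = k, meanSilhouette = mean(sil[, 3])))
  }
  attr(res, "best") <- res$k[which.max(res$meanSilhouette)]
  res
}
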