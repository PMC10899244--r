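# Mahalanobis-distance cluster-quality statistics: L-ratio and isolation
# distance.
#
# For a cluster C with N_c member spikes and feature covariance Sigma_C,
# the squared Mahalanobis distance of spike i is
#   MD2_i = (x_i - mu_C)' Sigma_C^{-1} (x_i - mu_C).
# The L-ratio is
#   L(C) = sum over i not in C of [1 - CDF_chi2_df(MD2_i)],
#   L_ratio = L(C) / N_c,
# with df the feature dimension (8 in the default feature space); a value
# below 0.05 indicates good separation.  The isolation distance is the
# N_c-th smallest MD2 among non-members, undefined (NA) when fewer than
# N_c non-members exist.  "Non-members" are all other detected spikes on
# the channel, whatever cluster they carry.

#' Squared Mahalanobis distances to a cluster
#'
#' Distances of every spike (members and non-members) from cluster
#' `clusterId`, using the cluster's own mean and unbiased covariance.  A
#' tiny ridge (`1e-9 * trace(Sigma)/d`) is added only when the covariance
#' conditioning exceeds 1e12, so degenerate fixtures do not crash; it is
#' off the mathematical path for realistic data.
#'
#' @param features n_spikes x d feature matrix.
#' @param labels integer cluster label per spike.
#' @param clusterId the cluster C.
#' @return numeric vector of MD^2, one per spike.
#' @export
mahalanobisSq <- function(features, labels, clusterId) {
  features <- as.matrix(features)
  member <- labels == clusterId
  nc <- sum(member)
  d <- ncol(features)
  if (nc <= d)
    stop(sprintf(
      "cluster %s has %d spikes; more than d = %d are needed to estimate its covariance",
      clusterId, nc, d))
  mu <- colMeans(features[member, , drop = FALSE])
  S <- stats::cov(features[member, , drop = FALSE])
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (ev[length(ev)] <= 0 || ev[1] / ev[length(ev)] > 1e12)
    S <- S + diag(1e-9 * sum(diag(S)) / d, d)
  md2 <- tryCatch(stats::mahalanobis(features, mu, S),
                  error = function(e)
                    stop("singular cluster covariance for cluster ",
                         clusterId))
  if (any(!is.finite(md2)))
    stop("singular cluster covariance for cluster ", clusterId)
  md2
}

#' L-ratio of a cluster
#'
#' @inheritParams mahalanobisSq
#' @param df degrees of freedom of the chi-square CDF; defaults to the
#'   feature dimension.
#' @return list with `L` (raw sum over non-members of
#'   `1 - CDF_chi2(MD^2)`), `LRatio` (`L / N_c`), `Nc` and `df`.
#' @export
lRatio <- function(features, labels, clusterId, df = ncol(features)) {
  md2 <- mahalanobisSq(features, labels, clusterId)
  member <- labels == clusterId
  L <- sum(1 - stats::pchisq(md2[!member], df = df))
  list(L = L, LRatio = L / sum(member), Nc = sum(member), df = df)
}

#' Isolation distance of a cluster
#'
#' The squared Mahalanobis distance of the N_c-th closest non-member
#' spike.  `NA` (undefined) when fewer than N_c non-members exist.
#'
#' @inheritParams mahalanobisSq
#' @return single numeric MD^2 value, or `NA_real_` when undefined.
#' @export
isolationDistance <- function(features, labels, clusterId) {
  md2 <- mahalanobisSq(features, labels, clusterId)
  member <- labels == clusterId
  nc <- sum(member)
  outside <- sort(md2[!member])
  if (length(outside) < nc) return(NA_real_)
  outside[nc]
}

#' Per-cluster quality report
#'
#' L-ratio and isolation distance for every cluster present in `labels`.
#' Clusters too small for a covariance estimate (N_c <= d) are reported
#' with `NA` statistics rather than failing the whole report.
#'
#' @inheritParams lRatio
#' @return data.frame with columns `cluster`, `n`, `L`, `L_ratio`,
#'   `isolation_distance`, `df`.
#' @export
clusterQuality <- function(features, labels, df = ncol(features)) {
  ks <- sort(unique(labels))
  rows <- lapply(ks, function(k) {
    n <- sum(labels == k)
    res <- tryCatch({
      lr <- lRatio(features, labels, k, df = df)
      iso <- isolationDistance(features, labels, k)
      data.frame(cluster = k, n = n, L = lr$L, L_ratio = lr$LRatio,
                 isolation_distance = iso, df = df)
    }, error = function(e)
      data.frame(cluster = k, n = n, L = NA_real_, L_ratio = NA_real_,
                 isolation_distance = NA_real_, df = df))
    res
  })
  do.call(rbind, rows)
}
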