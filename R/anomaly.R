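# Semi-supervised abnormal-behavior detection: reduce clip embeddings
# with PCA, density-cluster them with DBSCAN, and flag points outside
# every cluster as abnormal.  A continuous anomaly score (distance to the
# min_samples-th nearest neighbor in reduced space) supports a
# precision-recall curve and average precision.

#' Fit a PCA reduction of clip embeddings
#'
#' Mean-centered orthogonal projection onto the leading principal
#' components, ordered by explained variance.  Component signs are fixed
#' deterministically: the largest-magnitude loading of each component is
#' made positive.
#'
#' @param embeddings Numeric matrix, one row per clip.
#' @param n_components Number of components to keep.
#' @return List of class `pca_reduction` with `scores` (n x
#'   n_components), `rotation`, `center`, `explained_variance_ratio`.
#' @export
pca_fit_reduce <- function(embeddings, n_components) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  d <- ncol(embeddings)
  if (n < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  if (n_components > min(n, d))
    stop("n_components = ", n_components, " exceeds min(samples, dim) = ",
         min(n, d), call. = FALSE)
  fit <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
  rot <- fit$rotation[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  center <- fit$center
  scores <- sweep(embeddings, 2L, center, "-") %*% rot
  total_var <- sum(fit$sdev^2)
  evr <- (fit$sdev^2 / total_var)[seq_len(n_components)]
  structure(list(scores = scores, rotation = rot, center = center,
                 explained_variance_ratio = evr),
            class = "pca_reduction")
}

#' Apply a fitted PCA reduction to new embeddings
#'
#' @param fit A `pca_reduction`.
#' @param embeddings New embedding matrix.
#' @return Score matrix in the fitted reduced space.
#' @export
pca_transform <- function(fit, embeddings) {
  sweep(as.matrix(embeddings), 2L, fit$center, "-") %*% fit$rotation
}

#' Density-based clustering (DBSCAN)
#'
#' Standard contract: a core point has at least `min_samples` points
#' (including itself) within Euclidean distance `eps`; clusters are
#' maximal sets of density-connected points; points in no cluster are
#' labeled -1.  Border points reachable from several clusters are
#' assigned to the cluster of the lowest-index core point that reaches
#' them, making membership independent of input order.
#'
#' @param points Numeric matrix, one row per point.
#' @param eps Neighborhood radius (> 0).
#' @param min_samples Density threshold (>= 1).
#' @return Integer vector of cluster ids (1, 2, ...) with -1 for noise.
#' @export
dbscan_cluster <- function(points, eps, min_samples) {
  stopifnot(eps > 0, min_samples >= 1)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  dmat <- as.matrix(stats::dist(points))
  nb <- lapply(seq_len(n), function(i) which(dmat[i, ] <= eps))
  is_core <- vapply(nb, length, integer(1L)) >= min_samples
  labels <- rep(-1L, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || labels[i] != -1L) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    frontier <- i
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (q in frontier) {
        for (r in nb[[q]]) {
          if (labels[r] == -1L) {
            labels[r] <- cluster
            if (is_core[r]) nxt <- c(nxt, r)
          }
        }
      }
      frontier <- nxt
    }
  }
  # re-resolve border points: lowest-index core point within eps wins
  for (i in seq_len(n)) {
    if (is_core[i] || labels[i] == -1L) next
    cores_near <- nb[[i]][is_core[nb[[i]]]]
    if (length(cores_near) > 0L) labels[i] <- labels[min(cores_near)]
  }
  labels
}

# distance to the k-th nearest neighbor (excluding self) per point
knn_distance <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  dmat <- as.matrix(stats::dist(points))
  vapply(seq_len(n), function(i) {
    d <- sort(dmat[i, -i])
    d[min(k, length(d))]
  }, numeric(1L))
}

#' Default DBSCAN radius from the k-distance curve
#'
#' 1.5 times the median distance to the `min_samples`-th nearest
#' neighbor — a robust stand-in for the k-distance elbow.
#'
#' @param points Numeric matrix in reduced space.
#' @param min_samples Density threshold.
#' @return A positive scalar eps.
#' @export
eps_heuristic <- function(points, min_samples = 5L) {
  kd <- knn_distance(points, min_samples)
  eps <- 1.5 * stats::median(kd)
  if (eps <= 0) eps <- max(kd) * 1.5 + 1e-12
  eps
}

#' Detect abnormal clips from embeddings
#'
#' Pipeline: PCA reduction, then DBSCAN clustering in the reduced space.
#' Clips outside every cluster (label -1) are flagged abnormal.  The
#' continuous `anomaly_score` is the Euclidean distance to the
#' `min_samples`-th nearest neighbor in reduced space, so a
#' precision-recall curve exists with the DBSCAN flag as the operating
#' point.
#'
#' @param embeddings Numeric matrix, one row per clip.
#' @param pca_dims Number of principal components retained (default 8).
#' @param eps DBSCAN radius; `NULL` uses [eps_heuristic()].
#' @param min_samples DBSCAN density threshold (default 5).
#' @return An `anomaly_report`: a tibble with columns `clip`,
#'   `cluster_id` (-1 = no cluster), `anomaly_score`, `is_abnormal`, and
#'   attributes `params` (pca_dims, eps, min_samples, num_clusters) and
#'   `reduced` (the score matrix).
#' @export
detect_abnormal <- function(embeddings, pca_dims = 8L, eps = NULL,
                            min_samples = 5L) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < min_samples)
    stop("need at least min_samples = ", min_samples, " embeddings",
         call. = FALSE)
  pca_dims <- min(pca_dims, ncol(embeddings), n)
  red <- pca_fit_reduce(embeddings, pca_dims)
  pts <- red$scores
  if (is.null(eps)) eps <- eps_heuristic(pts, min_samples)
  labels <- dbscan_cluster(pts, eps, min_samples)
  score <- knn_distance(pts, min_samples)
  report <- tibble::tibble(
    clip = seq_len(n),
    cluster_id = labels,
    anomaly_score = score,
    is_abnormal = labels == -1L)
  attr(report, "params") <- list(
    pca_dims = pca_dims, eps = eps, min_samples = min_samples,
    num_clusters = length(setdiff(unique(labels), -1L)),
    explained_variance_ratio = red$explained_variance_ratio)
  attr(report, "reduced") <- pts
  class(report) <- c("anomaly_report", class(report))
  report
}

#' Average precision over a ranked anomaly scoring
#'
#' Sorts scores descending and accumulates precision times the recall
#' increment at each threshold (step-wise integral of the
#' precision-recall curve).  Tied scores are processed as a single
#' threshold.
#'
#' @param scores Numeric anomaly scores (higher = more anomalous).
#' @param truth Binary ground truth (1/TRUE = abnormal).
#' @return List of class `pr_metrics` with `ap`, `precision`, `recall`,
#'   `thresholds`, and operating-point counts `tp`, `fp`, `fn` at the
#'   final threshold.
#' @export
average_precision <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(scores) != length(truth))
    stop("scores and truth disagree in length", call. = FALSE)
  n_pos <- sum(truth)
  if (n_pos == 0L)
    stop("average precision is undefined without positives",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  # group tied scores: thresholds at the last index of each tie group
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tp_cum <- cumsum(y)
  fp_cum <- cumsum(1L - y)
  tp <- tp_cum[last_of_group]
  fp <- fp_cum[last_of_group]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  rec_prev <- c(0, recall[-length(recall)])
  ap <- sum(precision * (recall - rec_prev))
  structure(list(ap = ap, precision = precision, recall = recall,
                 thresholds = s[last_of_group],
                 tp = tp[length(tp)], fp = fp[length(fp)],
                 fn = n_pos - tp[length(tp)]),
            class = "pr_metrics")
}

#' @export
print.pr_metrics <- function(x, ...) {
  cat("<pr_metrics> AP =", format(x$ap, digits = 4),
      " (", length(x$thresholds), "thresholds )\n")
  invisible(x)
}

#' Write an anomaly report as JSON
#'
#' Per-clip records (clip id, cluster id, score, flag) plus the parameter
#' block, mirroring the tabular report.
#'
#' @param report An `anomaly_report`.
#' @param path Output JSON path.
#' @export
write_anomaly_report <- function(report, path) {
  payload <- list(
    params = attr(report, "params"),
    clips = lapply(seq_len(nrow(report)), function(i) list(
      clip = report$clip[i],
      cluster_id = report$cluster_id[i],
      anomaly_score = report$anomaly_score[i],
      is_abnormal = report$is_abnormal[i])))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
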