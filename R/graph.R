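# Skeleton graph: adjacency, degree normalization, partitioning, and the
# Gaussian-noise perturbation matrix used by the spatial graph convolution.

#' Default top-view mouse skeleton
#'
#' The 12 tracked body parts and the 11-edge anatomical tree connecting
#' them.  Edge indices are 1-based into the keypoint vector.
#'
#' @return For `mouse_keypoints()`, a character vector of 12 joint names.
#'   For `mouse_edges()`, a 2-column integer matrix of joint index pairs.
#' @export
mouse_keypoints <- function() {
  c("nose", "head", "L_ear", "R_ear", "neck",
    "L_forepaw", "R_forepaw", "spine_mid",
    "L_hindpaw", "R_hindpaw", "tail_base", "tail_tip")
}

#' @rdname mouse_keypoints
#' @export
mouse_edges <- function() {
  kp <- mouse_keypoints()
  pairs <- rbind(
    c("nose", "head"), c("head", "L_ear"), c("head", "R_ear"),
    c("head", "neck"), c("neck", "L_forepaw"), c("neck", "R_forepaw"),
    c("neck", "spine_mid"), c("spine_mid", "L_hindpaw"),
    c("spine_mid", "R_hindpaw"), c("spine_mid", "tail_base"),
    c("tail_base", "tail_tip"))
  matrix(match(pairs, kp), ncol = 2L,
         dimnames = list(NULL, c("from", "to")))
}

#' Build a skeleton joint graph
#'
#' Constructs the joint adjacency matrix A (with self-loops), its diagonal
#' degree matrix Lambda, and optionally the partition stack used by the
#' graph convolution.  The symmetric normalization is
#' Lambda^{-1/2} A Lambda^{-1/2}.
#'
#' @param k Number of joints.
#' @param edges 2-column matrix (or list of length-2 vectors) of 1-based
#'   joint index pairs; self-pairs are rejected, duplicates ignored.
#' @param strategy Partition strategy: `"distance"` splits the normalized
#'   adjacency into a self-loop part and a neighbor part; `"uniform"`
#'   keeps a single matrix.
#' @return An object of class `skeleton_graph` with elements `k`, `edges`,
#'   `A`, `Lambda`, `partitions`, `strategy`.
#' @export
build_skeleton_graph <- function(k, edges = NULL, strategy = "distance") {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  k <- as.integer(k)
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0) {
    if (any(edges < 1L | edges > k))
      stop("edge index out of range [1, ", k, "]", call. = FALSE)
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-pairs are not allowed in the edge list", call. = FALSE)
  }
  A <- diag(1, k)
  for (i in seq_len(nrow(edges))) {
    A[edges[i, 1L], edges[i, 2L]] <- 1
    A[edges[i, 2L], edges[i, 1L]] <- 1
  }
  Lambda <- diag(rowSums(A), k)
  g <- structure(
    list(k = k, edges = edges, A = A, Lambda = Lambda,
         partitions = list(), strategy = strategy),
    class = "skeleton_graph")
  g$partitions <- partition_adjacency(g, strategy)
  g
}

#' Symmetrically normalized adjacency
#'
#' @param g A `skeleton_graph`.
#' @return The k x k matrix Lambda^{-1/2} A Lambda^{-1/2}.
#' @export
normalize_adjacency <- function(g) {
  deg <- diag(g$Lambda)
  if (any(deg <= 0))
    stop("degenerate graph: joint with zero degree (no self-loop)",
         call. = FALSE)
  dinv <- diag(1 / sqrt(deg), g$k)
  dinv %*% g$A %*% dinv
}

#' Partition the normalized adjacency
#'
#' `"uniform"` returns the single normalized adjacency; `"distance"`
#' splits it into the self-loop (distance-0) and neighbor (distance-1)
#' parts.  The element-wise sum of the partitions always equals the
#' uniform matrix.
#'
#' @param g A `skeleton_graph`.
#' @param strategy `"uniform"` or `"distance"`.
#' @return List of k x k matrices.
#' @export
partition_adjacency <- function(g, strategy = c("distance", "uniform")) {
  strategy <- match.arg(strategy)
  An <- normalize_adjacency(g)
  if (strategy == "uniform") return(list(An))
  self_part <- diag(diag(An), g$k)
  list(self_part, An - self_part)
}

#' Noise configuration for the adjacency perturbation
#'
#' The spatial graph convolution can perturb its aggregation matrix with
#' G = Lambda . phi, where phi is a k x k draw of independent normals
#' with mean `mu` and standard deviation `sigma`.  With `sigma = 0` the
#' perturbation is the deterministic matrix `mu * Lambda`.
#'
#' @param mu Mean of the noise entries.
#' @param sigma Standard deviation of the noise entries (>= 0).  The
#'   default 0.02 keeps the perturbation G = Lambda . phi small relative
#'   to the entries of the normalized adjacency it is added to (degrees
#'   reach 5 on the default mouse tree, so G entries have sd up to 0.1).
#' @param resample_mode `"per_forward"` (a fresh draw every training
#'   forward pass) or `"fixed"`.
#' @param enabled_in_eval Apply noise at inference time too? Default off:
#'   the perturbation is a training-time mechanism.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(mu = 0, sigma = 0.02,
                         resample_mode = c("per_forward", "fixed"),
                         enabled_in_eval = FALSE) {
  stopifnot(sigma >= 0)
  structure(list(mu = mu, sigma = sigma,
                 resample_mode = match.arg(resample_mode),
                 enabled_in_eval = enabled_in_eval),
            class = "noise_config")
}

#' Draw a Gaussian noise matrix G = Lambda . phi
#'
#' Row i of G scales a N(mu, sigma^2) draw by the degree Lambda_ii, so the
#' perturbation respects the local connectivity scale of each joint.
#' Uses the current R random stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param g A `skeleton_graph`.
#' @param cfg A `noise_config`.
#' @return A k x k numeric matrix.
#' @export
sample_noise_matrix <- function(g, cfg) {
  k <- g$k
  phi <- matrix(stats::rnorm(k * k, mean = cfg$mu, sd = cfg$sigma), k, k)
  g$Lambda %*% phi
}

#' Read / write a graph configuration file
#'
#' YAML description of a skeleton graph: joint names, edge pairs (by
#' joint name), partition strategy, and the noise parameters mu/sigma.
#'
#' @param path YAML file path.
#' @return `read_graph_config` returns a list with `graph` (a
#'   `skeleton_graph`), `keypoints`, and `noise` (a `noise_config`).
#' @export
read_graph_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  kp <- as.character(cfg$keypoints)
  edges <- do.call(rbind, lapply(cfg$edges, function(e) {
    idx <- match(unlist(e), kp)
    if (any(is.na(idx)))
      stop("edge references unknown joint: ",
           paste(unlist(e), collapse = "-"), call. = FALSE)
    idx
  }))
  noise <- noise_config(mu = cfg$noise$mu %||% 0,
                        sigma = cfg$noise$sigma %||% 0.02)
  strategy <- cfg$strategy %||% "distance"
  list(graph = build_skeleton_graph(length(kp), edges, strategy),
       keypoints = kp, noise = noise)
}

#' @rdname read_graph_config
#' @param keypoints Joint names.
#' @param edges 2-column index matrix.
#' @param strategy Partition strategy tag.
#' @param noise A `noise_config`.
#' @export
write_graph_config <- function(path, keypoints = mouse_keypoints(),
                               edges = mouse_edges(),
                               strategy = "distance",
                               noise = noise_config()) {
  cfg <- list(
    keypoints = as.list(keypoints),
    edges = lapply(seq_len(nrow(edges)), function(i)
      list(keypoints[edges[i, 1L]], keypoints[edges[i, 2L]])),
    strategy = strategy,
    noise = list(mu = noise$mu, sigma = noise$sigma))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph> ", x$k, " joints, ", nrow(x$edges), " edges, ",
      length(x$partitions), " partition(s) [", x$strategy, "]\n", sep = "")
  invisible(x)
}
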