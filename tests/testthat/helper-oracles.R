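# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: explicit
# loops and closures only.

# graph aggregation: y[n,c,t,v] = sum_w x[n,c,t,w] * E[w,v]
oracle_joint_mix <- function(x, E) {
  d <- dim(x)
  y <- array(0, dim = c(d[1], d[2], d[3], ncol(E)))
  for (n in seq_len(d[1])) for (cc in seq_len(d[2]))
    for (t in seq_len(d[3])) for (v in seq_len(ncol(E)))
      for (w in seq_len(d[4]))
        y[n, cc, t, v] <- y[n, cc, t, v] + x[n, cc, t, w] * E[w, v]
  y
}

# full spatial graph conv: sum over partitions of (X %*% Ek) W_k + b
oracle_graph_conv <- function(x, E_list, W_list, b) {
  d <- dim(x)
  c_out <- ncol(W_list[[1]])
  y <- array(0, dim = c(d[1], d[2], d[3], d[4]))
  y <- array(0, dim = c(d[1], c_out, d[3], d[4]))
  for (kk in seq_along(E_list)) {
    agg <- oracle_joint_mix(x, E_list[[kk]])
    for (n in seq_len(d[1])) for (co in seq_len(c_out))
      for (t in seq_len(d[3])) for (v in seq_len(d[4]))
        for (ci in seq_len(d[2]))
          y[n, co, t, v] <- y[n, co, t, v] +
            agg[n, ci, t, v] * W_list[[kk]][ci, co]
  }
  for (co in seq_len(c_out)) y[, co, , ] <- y[, co, , ] + b[co]
  y
}

# dilated temporal convolution, same padding, explicit sliding window
oracle_dilated_conv <- function(x, W, b, dilation = 1L, stride = 1L) {
  d <- dim(x)
  k <- dim(W)[3]
  c_out <- dim(W)[2]
  pad <- ((k - 1L) * dilation) %/% 2L
  t_out <- floor((d[3] - 1L) / stride) + 1L
  half <- (k + 1L) %/% 2L
  y <- array(0, dim = c(d[1], c_out, t_out, d[4]))
  for (n in seq_len(d[1])) for (co in seq_len(c_out))
    for (to in seq_len(t_out)) for (v in seq_len(d[4])) {
      acc <- b[co]
      center <- (to - 1L) * stride + 1L
      for (j in seq_len(k)) {
        ti <- center + (j - half) * dilation
        if (ti >= 1L && ti <= d[3])
          for (ci in seq_len(d[2]))
            acc <- acc + x[n, ci, ti, v] * W[ci, co, j]
      }
      y[n, co, to, v] <- acc
    }
  y
}

# temporal max pool, window 3, same padding (-Inf outside)
oracle_tmaxpool <- function(x, stride = 1L) {
  d <- dim(x)
  t_out <- floor((d[3] - 1L) / stride) + 1L
  y <- array(-Inf, dim = c(d[1], d[2], t_out, d[4]))
  for (n in seq_len(d[1])) for (cc in seq_len(d[2]))
    for (to in seq_len(t_out)) for (v in seq_len(d[4])) {
      center <- (to - 1L) * stride + 1L
      for (ti in (center - 1L):(center + 1L))
        if (ti >= 1L && ti <= d[3])
          y[n, cc, to, v] <- max(y[n, cc, to, v], x[n, cc, ti, v])
    }
  y
}

# squeeze + excitation by direct formula evaluation
oracle_se <- function(x, W1, W2) {
  d <- dim(x)
  y <- array(0, dim = d)
  for (n in seq_len(d[1])) {
    z <- numeric(d[2])
    for (cc in seq_len(d[2])) {
      acc <- 0
      for (t in seq_len(d[3])) for (v in seq_len(d[4]))
        acc <- acc + x[n, cc, t, v]
      z[cc] <- acc / (d[3] * d[4])
    }
    h <- as.vector(W1 %*% z)
    h[h < 0] <- 0
    s <- 1 / (1 + exp(-as.vector(W2 %*% h)))
    for (cc in seq_len(d[2])) y[n, cc, , ] <- s[cc] * x[n, cc, , ]
  }
  y
}

# DBSCAN as literal density-reachability closure over the definition
oracle_dbscan_partition <- function(points, eps, min_samples) {
  points <- as.matrix(points)
  n <- nrow(points)
  dmat <- as.matrix(stats::dist(points))
  neigh <- lapply(seq_len(n), function(i) which(dmat[i, ] <= eps))
  core <- vapply(neigh, length, integer(1)) >= min_samples
  # cluster = connected component of the "core within eps of core" graph,
  # computed by repeated transitive closure over the membership matrix
  member <- vector("list", 0)
  assigned <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!core[i] || assigned[i]) next
    comp <- i
    repeat {
      grown <- unique(unlist(lapply(comp, function(q)
        neigh[[q]][core[neigh[[q]]]])))
      grown <- sort(union(comp, grown))
      if (identical(grown, comp)) break
      comp <- grown
    }
    assigned[comp] <- TRUE
    member[[length(member) + 1]] <- comp
  }
  # border points: non-core within eps of any core point of a component
  labels <- rep(-1L, n)
  for (ci in seq_along(member)) labels[member[[ci]]] <- ci
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != -1L) next
    cores_near <- neigh[[i]][core[neigh[[i]]]]
    if (length(cores_near) > 0) labels[i] <- labels[min(cores_near)]
  }
  labels
}

# canonical form of a clustering: sorted member sets + noise set, so two
# labelings can be compared independently of label ids
partition_sets <- function(labels) {
  ids <- sort(setdiff(unique(labels), -1L))
  sets <- lapply(ids, function(id) sort(which(labels == id)))
  sets <- sets[order(vapply(sets, `[`, integer(1), 1))]
  list(clusters = sets, noise = sort(which(labels == -1L)))
}

# top-k accuracy by explicit ranking loop (ties: lower class index first)
oracle_topk <- function(probs, labels, k) {
  n <- nrow(probs)
  hit <- 0
  for (i in seq_len(n)) {
    p <- probs[i, ]
    ranked <- integer(0)
    remaining <- seq_along(p)
    while (length(ranked) < k) {
      best <- remaining[1]
      for (j in remaining) if (p[j] > p[best]) best <- j
      ranked <- c(ranked, best)
      remaining <- setdiff(remaining, best)
    }
    if (labels[i] %in% ranked) hit <- hit + 1
  }
  hit / n
}

# average precision by enumerating every distinct score as a threshold
oracle_ap <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  n_pos <- sum(truth)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (th in thr) {
    sel <- scores >= th
    tp <- sum(truth[sel])
    fp <- sum(sel) - tp
    precision <- tp / (tp + fp)
    recall <- tp / n_pos
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# random small feature map
rand_fmap <- function(n, c, t, v) {
  array(stats::rnorm(n * c * t * v), dim = c(n, c, t, v))
}

# random connected-ish small graph for partition property checks
rand_graph <- function(k) {
  edges <- cbind(1:(k - 1), 2:k)  # path backbone
  extra <- which(stats::runif(k) < 0.3)
  for (i in extra) {
    others <- setdiff(seq_len(k), i)
    j <- others[sample.int(length(others), 1)]
    edges <- rbind(edges, sort(c(i, j)))
  }
  edges <- unique(edges)
  build_skeleton_graph(k, edges)
}
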