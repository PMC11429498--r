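# The enhanced spatio-temporal graph-convolutional encoder.
#
# Each block is: spatial graph convolution (optionally perturbed by a
# Gaussian noise matrix G = Lambda . phi) -> batch norm -> ReLU ->
# squeeze-and-excitation channel gate -> temporal stage (multi-branch
# dilated temporal convolution, or the classic kernel-9 temporal
# convolution) -> batch norm -> residual add -> ReLU.
# With all enhancement toggles off the stack reduces exactly to the
# original ST-GCN: y = Omega_1x1(X Abar) . M with Abar the symmetrically
# normalized adjacency and M a learnable edge-importance mask.

# ---- parameter initializers ------------------------------------------

gcn_init <- function(c_in, c_out, n_partitions, k) {
  list(
    W = lapply(seq_len(n_partitions), function(i)
      matrix(stats::rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out)),
    mask = lapply(seq_len(n_partitions), function(i) matrix(1, k, k)),
    b = rep(0, c_out))
}

se_init <- function(c, r) {
  if (c %% r != 0)
    stop("SE reduction ratio r = ", r, " must divide the channel count ",
         c, call. = FALSE)
  cr <- c %/% r
  list(W1 = matrix(stats::rnorm(cr * c, sd = sqrt(2 / c)), cr, c),
       W2 = matrix(stats::rnorm(c * cr, sd = sqrt(1 / cr)), c, cr),
       r = r)
}

# working width of the multi-branch temporal stage: largest multiple of 6
# not above 0.75 * c (gives 192 at c = 256, i.e. 32 channels per branch)
mtcn_width <- function(c) max(6L, 6L * ((3L * c) %/% (4L * 6L)))

mtcn_init <- function(c, c_mid = mtcn_width(c)) {
  if (c_mid %% 6L != 0L)
    stop("multi-branch temporal stage width must be divisible by 6",
         call. = FALSE)
  g <- c_mid %/% 6L
  list(
    entry = list(W = matrix(stats::rnorm(c * c_mid, sd = sqrt(2 / c)),
                            c, c_mid),
                 b = rep(0, c_mid)),
    conv1 = list(W = matrix(stats::rnorm(g * g, sd = sqrt(2 / g)), g, g),
                 b = rep(0, g)),
    dil = lapply(1:4, function(d) tconv_init(g, g, 3L)),
    exit = list(W = matrix(stats::rnorm(c_mid * c, sd = sqrt(2 / c_mid)),
                           c_mid, c),
                b = rep(0, c)),
    c_mid = c_mid)
}

#' Encoder / classifier configuration
#'
#' @param channels Output channel count per block; default the 9-block
#'   64-64-64-128-128-128-256-256-256 plan.
#' @param strides Temporal stride per block (1 or 2); defaults to stride 2
#'   at each channel-width change.
#' @param num_classes Number of behavior classes for the softmax head.
#' @param se_ratio Squeeze-and-excitation reduction ratio r (must divide
#'   every channel width); default 4.
#' @param noise_on,se_on,mtcn_on Enhancement toggles; all off reproduces
#'   the original ST-GCN with a kernel-9 temporal convolution.
#' @param noise A [noise_config()] for the adjacency perturbation.
#' @param in_channels Input channels (x, y, conf = 3).
#' @return An object of class `model_config`.
#' @export
model_config <- function(channels = c(64, 64, 64, 128, 128, 128,
                                      256, 256, 256),
                         strides = NULL,
                         num_classes = 4L,
                         se_ratio = 4L,
                         noise_on = TRUE, se_on = TRUE, mtcn_on = TRUE,
                         noise = noise_config(),
                         in_channels = 3L) {
  channels <- as.integer(channels)
  if (is.null(strides)) {
    strides <- rep(1L, length(channels))
    if (length(channels) > 1L)
      strides[which(diff(channels) != 0) + 1L] <- 2L
  }
  stopifnot(length(strides) == length(channels), all(strides %in% 1:2))
  structure(list(channels = channels, strides = as.integer(strides),
                 num_classes = as.integer(num_classes),
                 se_ratio = as.integer(se_ratio),
                 noise_on = noise_on, se_on = se_on, mtcn_on = mtcn_on,
                 noise = noise, in_channels = as.integer(in_channels)),
            class = "model_config")
}

#' Build an encoder + classifier model
#'
#' Initializes all parameters for the block stack described by `config`
#' over the joint graph `graph`.  Uses the current R random stream; call
#' [set.seed()] first for reproducible initialization.
#'
#' @param graph A [build_skeleton_graph()] result.
#' @param config A [model_config()].
#' @return An object of class `stgcn_model` with elements `graph`,
#'   `config`, `params`, `buffers`.
#' @export
build_model <- function(graph, config = model_config()) {
  np <- length(graph$partitions)
  ch <- config$channels
  blocks <- vector("list", length(ch))
  buffers <- vector("list", length(ch))
  c_in <- config$in_channels
  for (i in seq_along(ch)) {
    c_out <- ch[i]
    stride <- config$strides[i]
    bp <- list(
      gcn = gcn_init(c_in, c_out, np, graph$k),
      bn1 = bn_init(c_out),
      bn2 = bn_init(c_out),
      stride = stride)
    bb <- list(bn1 = bn_buffers_init(c_out), bn2 = bn_buffers_init(c_out))
    if (config$se_on) bp$se <- se_init(c_out, config$se_ratio)
    if (config$mtcn_on) bp$tcn <- mtcn_init(c_out)
    else bp$tcn <- tconv_init(c_out, c_out, 9L)
    if (c_in != c_out || stride != 1L) {
      bp$res <- list(W = matrix(stats::rnorm(c_in * c_out,
                                             sd = sqrt(2 / c_in)),
                                c_in, c_out),
                     b = rep(0, c_out),
                     bn = bn_init(c_out))
      bb$res_bn <- bn_buffers_init(c_out)
    }
    blocks[[i]] <- bp
    buffers[[i]] <- bb
    c_in <- c_out
  }
  emb_dim <- ch[length(ch)]
  params <- list(
    data_bn = bn_init(config$in_channels),
    blocks = blocks,
    head = list(W = matrix(stats::rnorm(emb_dim * config$num_classes,
                                        sd = sqrt(1 / emb_dim)),
                           emb_dim, config$num_classes),
                b = rep(0, config$num_classes)))
  bufs <- list(data_bn = bn_buffers_init(config$in_channels),
               blocks = buffers)
  if (identical(config$noise$resample_mode, "fixed"))
    for (i in seq_along(blocks))
      params$blocks[[i]]$gcn$G_fixed <- sample_noise_matrix(graph,
                                                            config$noise)
  structure(list(graph = graph, config = config, params = params,
                 buffers = bufs, embedding_dim = emb_dim),
            class = "stgcn_model")
}

#' @export
print.stgcn_model <- function(x, ...) {
  cat("<stgcn_model> ", length(x$config$channels), " blocks, ",
      x$graph$k, " joints, embedding dim ", x$embedding_dim,
      ", ", x$config$num_classes, " classes\n", sep = "")
  cat("  toggles: noise=", x$config$noise_on, " se=", x$config$se_on,
      " mtcn=", x$config$mtcn_on, "\n", sep = "")
  invisible(x)
}

# ---- spatial graph convolution ---------------------------------------

# G is NULL (no perturbation) or a k x k matrix shared by all partitions
gcn_fwd <- function(x, p, partitions, G = NULL) {
  np <- length(partitions)
  y <- NULL
  caches <- vector("list", np)
  E <- vector("list", np)
  for (kk in seq_len(np)) {
    Ek <- partitions[[kk]]
    if (!is.null(G)) Ek <- Ek + G
    Ek <- Ek * p$mask[[kk]]
    jm <- joint_mix_fwd(x, Ek)
    cm <- chan_mix_fwd(jm$out, p$W[[kk]])
    y <- if (is.null(y)) cm$out else y + cm$out
    caches[[kk]] <- list(jm = jm$cache, cm = cm$cache)
    E[[kk]] <- Ek
  }
  y <- add_channel_bias(y, p$b)
  list(out = y, cache = list(caches = caches, E = E, G = G,
                             partitions = partitions))
}

gcn_bwd <- function(dy, cache, p) {
  np <- length(cache$caches)
  dx <- NULL
  dW <- vector("list", np)
  dmask <- vector("list", np)
  db <- colSums(to_cmat(dy))
  for (kk in seq_len(np)) {
    ck <- cache$caches[[kk]]
    cb <- chan_mix_bwd(dy, ck$cm, p$W[[kk]], has_bias = FALSE)
    dW[[kk]] <- cb$dW
    jb <- joint_mix_bwd(cb$dx, ck$jm, cache$E[[kk]])
    dx <- if (is.null(dx)) jb$dx else dx + jb$dx
    base <- cache$partitions[[kk]]
    if (!is.null(cache$G)) base <- base + cache$G
    dmask[[kk]] <- jb$dE * base
  }
  list(dx = dx, grads = list(W = dW, mask = dmask, b = db))
}

#' Spatial graph convolution over a skeleton graph
#'
#' Aggregates joint features over each (optionally noise-perturbed)
#' normalized adjacency partition, applies the learnable edge-importance
#' mask elementwise, mixes channels with 1x1 weights and sums the
#' partition results.  With `mu = sigma = 0` this is the plain ST-GCN
#' spatial convolution.
#'
#' @param x Feature map array (N, C_in, T, V).
#' @param g A `skeleton_graph` (with partitions built).
#' @param params Layer parameters as produced by the model builder:
#'   per-partition weight matrices `W`, per-partition masks `mask`, bias
#'   `b`, optionally `noise` (a [noise_config()]).
#' @param train Sample a fresh noise matrix (training mode)?
#' @return Feature map array (N, C_out, T, V).
#' @export
spatial_graph_conv <- function(x, g, params, train = TRUE) {
  if (dim(x)[4L] != g$k)
    stop("joint dimension of x (", dim(x)[4L],
         ") does not match graph (", g$k, ")", call. = FALSE)
  G <- NULL
  cfg <- params$noise
  if (!is.null(cfg) && (cfg$sigma > 0 || cfg$mu != 0) &&
      (train || isTRUE(cfg$enabled_in_eval)))
    G <- sample_noise_matrix(g, cfg)
  gcn_fwd(x, params, g$partitions, G)$out
}

# ---- squeeze-and-excitation ------------------------------------------

#' Squeeze: global average over time and joints per channel
#'
#' @param u Feature map array (N, C, T, V).
#' @return N x C matrix of channel means.
#' @export
se_squeeze <- function(u) {
  gpool_fwd(u)$out
}

se_fwd <- function(x, p) {
  d <- dim(x)
  gp <- gpool_fwd(x)
  z <- gp$out                         # N x C
  h <- z %*% t(p$W1)                  # N x C/r
  hr <- h; hr[hr < 0] <- 0
  pre2 <- hr %*% t(p$W2)              # N x C
  s <- sigmoid(pre2)
  xm <- matrix(x, nrow = d[1L] * d[2L])
  ym <- xm * as.vector(s)
  y <- array(ym, dim = d)
  list(out = y, cache = list(x = x, z = z, h = h, hr = hr, s = s,
                             dims = d))
}

se_bwd <- function(dy, cache, p) {
  d <- cache$dims
  nrowm <- d[1L] * d[2L]
  dym <- matrix(dy, nrow = nrowm)
  xm <- matrix(cache$x, nrow = nrowm)
  s <- cache$s
  ds <- matrix(rowSums(dym * xm), nrow = d[1L])
  dx1 <- array(dym * as.vector(s), dim = d)
  dpre2 <- ds * s * (1 - s)
  dW2 <- crossprod(dpre2, cache$hr)
  dhr <- dpre2 %*% p$W2
  dh <- dhr * (cache$h > 0)
  dW1 <- crossprod(dh, cache$z)
  dz <- dh %*% p$W1
  dx2 <- gpool_bwd(dz, d)
  list(dx = dx1 + dx2, grads = list(W1 = dW1, W2 = dW2))
}

#' Squeeze-and-excitation channel recalibration
#'
#' Gates each channel by s = sigmoid(W2 ReLU(W1 z)) computed from the
#' channel means z of the same input, then rescales: x_c <- s_c * x_c.
#' All gates lie strictly in (0, 1), so no channel is amplified.
#'
#' @param u Feature map array (N, C, T, V).
#' @param sp SE parameters (`W1` of shape (C/r) x C, `W2` of shape
#'   C x (C/r), ratio `r`).
#' @return Feature map of the same shape.
#' @export
se_recalibrate <- function(u, sp) {
  if (nrow(sp$W1) * sp$r != dim(u)[2L])
    stop("SE weight shapes inconsistent with channel count", call. = FALSE)
  se_fwd(u, sp)$out
}

# ---- multi-branch temporal stage -------------------------------------

cat_channels <- function(pieces) {
  d1 <- dim(pieces[[1L]])
  ctot <- sum(vapply(pieces, function(p) dim(p)[2L], integer(1L)))
  out <- array(0, dim = c(d1[1L], ctot, d1[3L], d1[4L]))
  at <- 0L
  for (p in pieces) {
    cc <- dim(p)[2L]
    out[, (at + 1L):(at + cc), , ] <- p
    at <- at + cc
  }
  out
}

subsample_time <- function(x, stride) {
  if (stride == 1L) return(x)
  x[, , seq(1L, dim(x)[3L], by = stride), , drop = FALSE]
}

mtcn_fwd <- function(x, p, stride = 1L) {
  d <- dim(x)
  en <- chan_mix_fwd(x, p$entry$W, p$entry$b)
  er <- relu_fwd(en$out)
  g <- p$c_mid %/% 6L
  xs <- lapply(0:5, function(i)
    er$out[, (i * g + 1L):((i + 1L) * g), , , drop = FALSE])
  # branch 1: 1x1 conv (with temporal subsampling at stride > 1)
  b1in <- subsample_time(xs[[1L]], stride)
  b1 <- chan_mix_fwd(b1in, p$conv1$W, p$conv1$b)
  # branch 2: temporal max pool, window 3
  b2 <- tmaxpool_fwd(xs[[2L]], window = 3L, stride = stride)
  # branches 3-6: kernel-3 temporal conv, dilations 1..4
  bd <- lapply(1:4, function(i)
    tconv_fwd(xs[[i + 2L]], p$dil[[i]], stride = stride, dilation = i))
  pieces <- c(list(b1$out, b2$out), lapply(bd, `[[`, "out"))
  cc <- cat_channels(pieces)
  ex <- chan_mix_fwd(cc, p$exit$W, p$exit$b)
  list(out = ex$out,
       cache = list(en = en$cache, er = er$cache, b1 = b1$cache,
                    b2 = b2$cache, bd = lapply(bd, `[[`, "cache"),
                    ex = ex$cache, g = g, stride = stride, dims = d))
}

mtcn_bwd <- function(dy, cache, p) {
  g <- cache$g
  exb <- chan_mix_bwd(dy, cache$ex, p$exit$W)
  dcc <- exb$dx
  slice <- function(i) dcc[, ((i - 1L) * g + 1L):(i * g), , , drop = FALSE]
  b1b <- chan_mix_bwd(slice(1L), cache$b1, p$conv1$W)
  # undo the temporal subsampling of branch 1
  d1 <- dim(b1b$dx)
  stride <- cache$stride
  t_full <- cache$dims[3L]
  db1 <- if (stride == 1L) b1b$dx else {
    tmp <- array(0, dim = c(d1[1L], d1[2L], t_full, d1[4L]))
    tmp[, , seq(1L, t_full, by = stride), ] <- b1b$dx
    tmp
  }
  db2 <- tmaxpool_bwd(slice(2L), cache$b2)
  dbd <- lapply(1:4, function(i)
    tconv_bwd(slice(i + 2L), cache$bd[[i]], p$dil[[i]]))
  der <- cat_channels(c(list(db1, db2), lapply(dbd, `[[`, "dx")))
  den <- relu_bwd(der, cache$er)
  enb <- chan_mix_bwd(den, cache$en, p$entry$W)
  list(dx = enb$dx,
       grads = list(
         entry = list(W = enb$dW, b = enb$db),
         conv1 = list(W = b1b$dW, b = b1b$db),
         dil = lapply(dbd, function(b) list(W = b$dW, b = b$db)),
         exit = list(W = exb$dW, b = exb$db)))
}

#' Multi-branch temporal convolution
#'
#' An entry 1x1 convolution widens/narrows the features to a working
#' width divisible by six and splits them into six equal channel groups;
#' the groups pass through a 1x1 convolution branch, a window-3 temporal
#' max-pool branch, and four kernel-3 temporal convolution branches with
#' dilations 1-4; the outputs are concatenated and remixed by an exit
#' 1x1 convolution.  Temporal length is preserved at stride 1 (same
#' padding) and halved at stride 2.
#'
#' @param x Feature map array (N, C, T, V).
#' @param mp Parameters from the model builder (`entry`, `conv1`, `dil`,
#'   `exit`, `c_mid`).
#' @param stride Temporal stride (1 or 2).
#' @return Feature map array (N, C, T_out, V).
#' @export
mtcn <- function(x, mp, stride = 1L) {
  if (mp$c_mid %% 6L != 0L)
    stop("working channel width must be divisible by 6", call. = FALSE)
  mtcn_fwd(x, mp, stride = stride)$out
}

# ---- full block -------------------------------------------------------

block_fwd <- function(x, bp, bb, graph, config, train = TRUE,
                      bn_momentum = BN_MOMENTUM, use_noise = NULL) {
  G <- NULL
  ncfg <- config$noise
  if (is.null(use_noise))
    use_noise <- config$noise_on && (train || isTRUE(ncfg$enabled_in_eval))
  if (use_noise) {
    G <- if (identical(ncfg$resample_mode, "fixed")) bp$gcn$G_fixed
         else sample_noise_matrix(graph, ncfg)
  }
  gc <- gcn_fwd(x, bp$gcn, graph$partitions, G)
  n1 <- bn_fwd(gc$out, bp$bn1, bb$bn1, train, bn_momentum)
  r1 <- relu_fwd(n1$out)
  h <- r1$out
  se_cache <- NULL
  if (config$se_on) {
    sc <- se_fwd(h, bp$se)
    h <- sc$out
    se_cache <- sc$cache
  }
  if (config$mtcn_on) {
    tc <- mtcn_fwd(h, bp$tcn, stride = bp$stride)
  } else {
    tc <- tconv_fwd(h, bp$tcn, stride = bp$stride, dilation = 1L)
  }
  n2 <- bn_fwd(tc$out, bp$bn2, bb$bn2, train, bn_momentum)
  res_cache <- NULL
  if (is.null(bp$res)) {
    res <- x
  } else {
    rs <- subsample_time(x, bp$stride)
    rc <- chan_mix_fwd(rs, bp$res$W, bp$res$b)
    rn <- bn_fwd(rc$out, bp$res$bn, bb$res_bn, train, bn_momentum)
    res <- rn$out
    res_cache <- list(rc = rc$cache, rn = rn$cache)
    bb$res_bn <- rn$buf
  }
  pre <- n2$out + res
  out <- relu_fwd(pre)
  bb$bn1 <- n1$buf
  bb$bn2 <- n2$buf
  list(out = out$out, buf = bb,
       cache = list(gc = gc$cache, n1 = n1$cache, r1 = r1$cache,
                    se = se_cache, tc = tc$cache, n2 = n2$cache,
                    res = res_cache, relu_out = out$cache,
                    x_dims = dim(x)))
}

block_bwd <- function(dy, cache, bp, config) {
  dpre <- relu_bwd(dy, cache$relu_out)
  grads <- list()
  # residual path
  if (is.null(cache$res)) {
    dres <- dpre
  } else {
    rnb <- bn_bwd(dpre, cache$res$rn, bp$res$bn)
    rcb <- chan_mix_bwd(rnb$dx, cache$res$rc, bp$res$W)
    grads$res <- list(W = rcb$dW, b = rcb$db,
                      bn = list(gamma = rnb$dgamma, beta = rnb$dbeta))
    # undo temporal subsampling
    d0 <- cache$x_dims
    if (bp$stride == 1L) {
      dres <- rcb$dx
    } else {
      dres <- array(0, dim = d0)
      dres[, , seq(1L, d0[3L], by = bp$stride), ] <- rcb$dx
    }
  }
  # main path
  n2b <- bn_bwd(dpre, cache$n2, bp$bn2)
  grads$bn2 <- list(gamma = n2b$dgamma, beta = n2b$dbeta)
  if (config$mtcn_on) {
    tb <- mtcn_bwd(n2b$dx, cache$tc, bp$tcn)
    grads$tcn <- tb$grads
  } else {
    tb <- tconv_bwd(n2b$dx, cache$tc, bp$tcn)
    grads$tcn <- list(W = tb$dW, b = tb$db)
  }
  dh <- tb$dx
  if (config$se_on) {
    sb <- se_bwd(dh, cache$se, bp$se)
    grads$se <- sb$grads
    dh <- sb$dx
  }
  dr1 <- relu_bwd(dh, cache$r1)
  n1b <- bn_bwd(dr1, cache$n1, bp$bn1)
  grads$bn1 <- list(gamma = n1b$dgamma, beta = n1b$dbeta)
  gb <- gcn_bwd(n1b$dx, cache$gc, bp$gcn)
  grads$gcn <- gb$grads
  list(dx = gb$dx + dres, grads = grads)
}

#' Run one enhanced ST-GCN block
#'
#' Composition: spatial graph convolution -> batch norm -> ReLU -> SE
#' gate (if enabled) -> temporal stage (multi-branch or kernel-9
#' convolution) -> batch norm -> residual add -> ReLU.  The residual is
#' the identity when shapes match, otherwise a strided 1x1 convolution.
#'
#' @param x Feature map array (N, C_in, T, V).
#' @param graph A `skeleton_graph`.
#' @param block_params One element of `model$params$blocks`.
#' @param block_buffers Matching element of `model$buffers$blocks`.
#' @param config The `model_config`.
#' @param train Training mode (batch statistics, noise sampling)?
#' @return Feature map array (N, C_out, T_out, V).
#' @export
stgcn_block <- function(x, graph, block_params, block_buffers, config,
                        train = FALSE) {
  block_fwd(x, block_params, block_buffers, graph, config, train)$out
}

# ---- full model forward / backward -----------------------------------

# x5: rank-5 (N, C, T, V, M); folds M = 1 into rank-4
fold_m <- function(x5) {
  d <- dim(x5)
  if (length(d) == 4L) return(x5)
  stopifnot(d[5L] == 1L)
  array(x5, dim = d[1:4])
}

model_fwd <- function(model, x, train = TRUE,
                      bn_momentum = BN_MOMENTUM, use_noise = NULL) {
  x <- fold_m(x)
  if (dim(x)[4L] != model$graph$k)
    stop("input joint count (", dim(x)[4L],
         ") does not match the model graph (", model$graph$k, ")",
         call. = FALSE)
  p <- model$params
  b <- model$buffers
  dbn <- bn_fwd(x, p$data_bn, b$data_bn, train, bn_momentum)
  b$data_bn <- dbn$buf
  h <- dbn$out
  caches <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    bf <- block_fwd(h, p$blocks[[i]], b$blocks[[i]], model$graph,
                    model$config, train, bn_momentum, use_noise)
    h <- bf$out
    b$blocks[[i]] <- bf$buf
    caches[[i]] <- bf$cache
  }
  gp <- gpool_fwd(h)
  emb <- gp$out
  lf <- linear_fwd(emb, p$head$W, p$head$b)
  model$buffers <- b
  list(embedding = emb, logits = lf$out, model = model,
       cache = list(dbn = dbn$cache, blocks = caches, gp = gp$cache,
                    head = lf$cache))
}

model_bwd <- function(model, cache, dlogits) {
  p <- model$params
  hb <- linear_bwd(dlogits, cache$head, p$head$W)
  grads <- list(head = list(W = hb$dW, b = hb$db))
  dh <- gpool_bwd(hb$dx, cache$gp)
  gblocks <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    bb <- block_bwd(dh, cache$blocks[[i]], p$blocks[[i]], model$config)
    gblocks[[i]] <- bb$grads
    dh <- bb$dx
  }
  dbnb <- bn_bwd(dh, cache$dbn, p$data_bn)
  grads$data_bn <- list(gamma = dbnb$dgamma, beta = dbnb$dbeta)
  grads$blocks <- gblocks
  grads
}

#' Encode clips into fixed-length embeddings
#'
#' Runs the full encoder in evaluation mode (running batch-norm
#' statistics, noise disabled unless configured otherwise): input batch
#' normalization, the block stack, then global average pooling over time
#' and joints.
#'
#' @param model An `stgcn_model`.
#' @param x A `clip_dataset`, a `skeleton_sequence`, or a rank-5 tensor.
#' @return A numeric matrix, one row per clip, `model$embedding_dim`
#'   columns.
#' @export
encode_clips <- function(model, x) {
  tensor <- clip_tensor(x)
  model_fwd(model, tensor, train = FALSE)$embedding
}

clip_tensor <- function(x) {
  if (inherits(x, "clip_dataset")) stack_clips(x)
  else if (inherits(x, "skeleton_sequence")) x$data
  else x
}

#' Classify embeddings with the softmax head
#'
#' @param model An `stgcn_model` (or anything with `$params$head`).
#' @param embeddings Matrix of clip embeddings (rows = clips).
#' @return Matrix of class probabilities; rows sum to 1.
#' @export
classify <- function(model, embeddings) {
  if (is.null(dim(embeddings)))
    embeddings <- matrix(embeddings, nrow = 1L)
  head <- model$params$head
  logits <- sweep(embeddings %*% head$W, 2L, head$b, "+")
  p <- softmax_rows(logits)
  colnames(p) <- NULL
  p
}

#' Predict class probabilities for clips
#'
#' @param object An `stgcn_model`.
#' @param newdata A `clip_dataset` (or tensor).
#' @param ... Unused.
#' @return Matrix of class probabilities, one row per clip.
#' @export
predict.stgcn_model <- function(object, newdata, ...) {
  classify(object, encode_clips(object, newdata))
}

# ---- parameter bookkeeping -------------------------------------------

# recursively count numeric leaves; `skip` names are excluded (buffers,
# fixed noise draws, scalar tags)
count_params <- function(p) {
  if (is.numeric(p)) return(length(p))
  if (!is.list(p)) return(0L)
  skip <- c("G_fixed", "r", "c_mid", "stride")
  nm <- names(p)
  total <- 0L
  for (i in seq_along(p)) {
    if (!is.null(nm) && nm[i] %in% skip) next
    total <- total + count_params(p[[i]])
  }
  total
}

#' Save / load a model checkpoint
#'
#' Single-file archive of all parameter tensors, batch-norm running
#' statistics, the model configuration and the graph.
#'
#' @param model An `stgcn_model`.
#' @param path Checkpoint file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "stgcnad_model", version = 1L, model = model),
          path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt checkpoint: ", conditionMessage(e), call. = FALSE))
  if (!is.list(payload) || !identical(payload$format, "stgcnad_model"))
    stop("not a model checkpoint", call. = FALSE)
  payload$model
}
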