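# Low-level differentiable primitives on rank-4 feature maps.
#
# A feature map is a plain numeric array with dim (N, C, T, V):
# batch, channels, time, joints.  All primitives return both the output
# and the cache needed for the backward pass; backward functions return
# the input gradient and parameter gradients.  Column-major layout is
# exploited throughout: (N, C) are the fastest-varying dimensions, so
# matrix(x, nrow = N * C) is the (sample*channel) x (time*joint) view,
# and matrix(x, ncol = V) is the (sample*channel*time) x joint view.

# ---- layout helpers ---------------------------------------------------

# (N, C, T, V) -> (N*T*V) x C matrix (rows vary fastest over N, then T, V)
to_cmat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 3L, 4L, 2L))
  dim(m) <- c(d[1L] * d[3L] * d[4L], d[2L])
  m
}

from_cmat <- function(m, n, t, v) {
  cc <- ncol(m)
  dim(m) <- c(n, t, v, cc)
  aperm(m, c(1L, 4L, 2L, 3L))
}

# ---- 1x1 channel-mixing convolution -----------------------------------

# y[n,co,t,v] = sum_ci x[n,ci,t,v] W[ci,co] (+ b[co])
chan_mix_fwd <- function(x, W, b = NULL) {
  d <- dim(x)
  xm <- to_cmat(x)
  ym <- xm %*% W
  if (!is.null(b)) ym <- sweep(ym, 2L, b, "+")
  list(out = from_cmat(ym, d[1L], d[3L], d[4L]),
       cache = list(xm = xm, dims = d))
}

chan_mix_bwd <- function(dy, cache, W, has_bias = TRUE) {
  d <- dim(dy)
  dym <- to_cmat(dy)
  dW <- crossprod(cache$xm, dym)
  db <- if (has_bias) colSums(dym) else NULL
  dxm <- dym %*% t(W)
  din <- cache$dims
  list(dx = from_cmat(dxm, din[1L], din[3L], din[4L]), dW = dW, db = db)
}

# ---- joint-mixing (graph aggregation) ---------------------------------

# y[n,c,t,v] = sum_w x[n,c,t,w] E[w,v]
joint_mix_fwd <- function(x, E) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4L])
  ym <- xm %*% E
  y <- array(ym, dim = c(d[1L], d[2L], d[3L], ncol(E)))
  list(out = y, cache = list(xm = xm, dims = d))
}

joint_mix_bwd <- function(dy, cache, E) {
  dym <- matrix(dy, ncol = dim(dy)[4L])
  dE <- crossprod(cache$xm, dym)
  dxm <- dym %*% t(E)
  list(dx = array(dxm, dim = cache$dims), dE = dE)
}

# ---- batch normalization over (N, T, V) per channel -------------------

bn_init <- function(c_out) {
  list(gamma = rep(1, c_out), beta = rep(0, c_out))
}

bn_buffers_init <- function(c_out) {
  list(mean = rep(0, c_out), var = rep(1, c_out))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd <- function(x, p, buf, train = TRUE, momentum = BN_MOMENTUM) {
  d <- dim(x)
  xm <- to_cmat(x)
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu, "-")
    va <- colMeans(xc * xc)
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    buf$var  <- (1 - momentum) * buf$var  + momentum * va
  } else {
    mu <- buf$mean
    va <- buf$var
    xc <- sweep(xm, 2L, mu, "-")
  }
  inv <- 1 / sqrt(va + BN_EPS)
  xhat <- sweep(xc, 2L, inv, "*")
  ym <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(out = from_cmat(ym, d[1L], d[3L], d[4L]), buf = buf,
       cache = list(xhat = xhat, inv = inv, dims = d, train = train))
}

bn_bwd <- function(dy, cache, p) {
  d <- cache$dims
  m <- d[1L] * d[3L] * d[4L]
  dym <- to_cmat(dy)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, p$gamma, "*")
  if (cache$train) {
    # standard batch-norm backward through the batch statistics
    t1 <- sweep(dxhat, 2L, colSums(dxhat) / m, "-")
    t2 <- sweep(cache$xhat, 2L, colSums(dxhat * cache$xhat) / m, "*")
    dxm <- sweep(t1 - t2, 2L, cache$inv, "*")
  } else {
    dxm <- sweep(dxhat, 2L, cache$inv, "*")
  }
  list(dx = from_cmat(dxm, d[1L], d[3L], d[4L]),
       dgamma = dgamma, dbeta = dbeta)
}

# ---- ReLU -------------------------------------------------------------

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  list(out = y, cache = x > 0)
}

relu_bwd <- function(dy, cache) {
  dy * cache
}

# ---- temporal padding / slicing ---------------------------------------

pad_time <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, dim = c(d[1L], d[2L], d[3L] + 2L * pad, d[4L]))
  xp[, , (pad + 1L):(pad + d[3L]), ] <- x
  xp
}

# output length of a same-padded temporal op at the given stride
t_out_len <- function(t_in, stride) as.integer(floor((t_in - 1) / stride) + 1L)

# ---- dilated temporal convolution (kernel K, stride s, same padding) --

tconv_init <- function(c_in, c_out, k) {
  list(W = array(stats::rnorm(c_in * c_out * k, sd = sqrt(2 / (c_in * k))),
                 dim = c(c_in, c_out, k)),
       b = rep(0, c_out))
}

tconv_fwd <- function(x, p, stride = 1L, dilation = 1L) {
  d <- dim(x)
  k <- dim(p$W)[3L]
  pad <- ((k - 1L) * dilation) %/% 2L
  xp <- pad_time(x, pad)
  t_out <- t_out_len(d[3L], stride)
  centers <- (seq_len(t_out) - 1L) * stride + 1L + pad
  half <- (k + 1L) %/% 2L
  y <- NULL
  caches <- vector("list", k)
  idxs <- vector("list", k)
  for (j in seq_len(k)) {
    idx <- centers + (j - half) * dilation
    slice <- xp[, , idx, , drop = FALSE]
    cm <- chan_mix_fwd(slice, p$W[, , j])
    y <- if (is.null(y)) cm$out else y + cm$out
    caches[[j]] <- cm$cache
    idxs[[j]] <- idx
  }
  y <- add_channel_bias(y, p$b)
  list(out = y, cache = list(caches = caches, idxs = idxs, pad = pad,
                             dims = d, k = k))
}

add_channel_bias <- function(y, b) {
  d <- dim(y)
  ym <- to_cmat(y)
  ym <- sweep(ym, 2L, b, "+")
  from_cmat(ym, d[1L], d[3L], d[4L])
}

tconv_bwd <- function(dy, cache, p) {
  d <- cache$dims
  k <- cache$k
  dW <- array(0, dim = dim(p$W))
  db <- colSums(to_cmat(dy))
  dxp <- array(0, dim = c(d[1L], d[2L], d[3L] + 2L * cache$pad, d[4L]))
  for (j in seq_len(k)) {
    bk <- chan_mix_bwd(dy, cache$caches[[j]], p$W[, , j], has_bias = FALSE)
    dW[, , j] <- bk$dW
    idx <- cache$idxs[[j]]
    dxp[, , idx, ] <- dxp[, , idx, , drop = FALSE] + bk$dx
  }
  dx <- dxp[, , (cache$pad + 1L):(cache$pad + d[3L]), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# ---- temporal max pooling (window 3, same padding) --------------------

tmaxpool_fwd <- function(x, window = 3L, stride = 1L) {
  d <- dim(x)
  pad <- (window - 1L) %/% 2L
  xp <- pad_time(x, pad, fill = -Inf)
  t_out <- t_out_len(d[3L], stride)
  centers <- (seq_len(t_out) - 1L) * stride + 1L + pad
  half <- (window + 1L) %/% 2L
  y <- NULL
  which_tap <- NULL
  idxs <- vector("list", window)
  for (j in seq_len(window)) {
    idx <- centers + (j - half)
    slice <- xp[, , idx, , drop = FALSE]
    if (is.null(y)) {
      y <- slice
      which_tap <- array(1L, dim = dim(slice))
    } else {
      upd <- slice > y
      y[upd] <- slice[upd]
      which_tap[upd] <- j
    }
    idxs[[j]] <- idx
  }
  list(out = y, cache = list(which_tap = which_tap, idxs = idxs, pad = pad,
                             dims = d, window = window))
}

tmaxpool_bwd <- function(dy, cache) {
  d <- cache$dims
  dxp <- array(0, dim = c(d[1L], d[2L], d[3L] + 2L * cache$pad, d[4L]))
  for (j in seq_len(cache$window)) {
    sel <- cache$which_tap == j
    g <- array(0, dim = dim(dy))
    g[sel] <- dy[sel]
    idx <- cache$idxs[[j]]
    dxp[, , idx, ] <- dxp[, , idx, , drop = FALSE] + g
  }
  dxp[, , (cache$pad + 1L):(cache$pad + d[3L]), , drop = FALSE]
}

# ---- global average pooling over (T, V) -------------------------------

gpool_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1L] * d[2L])
  y <- matrix(rowMeans(m), nrow = d[1L])
  list(out = y, cache = d)
}

gpool_bwd <- function(dy, cache) {
  d <- cache
  scale <- 1 / (d[3L] * d[4L])
  array(as.vector(dy) * scale, dim = d)
}

# ---- linear head + softmax cross-entropy ------------------------------

linear_fwd <- function(x, W, b) {
  list(out = sweep(x %*% W, 2L, b, "+"), cache = x)
}

linear_bwd <- function(dy, cache, W) {
  list(dx = dy %*% t(W), dW = crossprod(cache, dy), db = colSums(dy))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# labels are 1-based class indices; returns mean cross-entropy and dlogits
softmax_xent <- function(logits, labels) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  picked <- p[cbind(seq_len(n), labels)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), labels)] <-
    dlogits[cbind(seq_len(n), labels)] - 1
  dlogits <- dlogits / n
  list(loss = loss, probs = p, dlogits = dlogits)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
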