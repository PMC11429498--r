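# Layer-level checks against independent brute-force oracles, plus
# finite-difference verification of the hand-written backward passes.

test_that("spatial graph conv equals the per-node summation oracle", {
  set.seed(21)
  for (trial in 1:20) {
    k <- sample(2:5, 1)
    g <- rand_graph(k)
    c_in <- sample(1:4, 1); c_out <- sample(1:4, 1)
    x <- rand_fmap(sample(1:2, 1), c_in, sample(2:6, 1), k)
    p <- gcn_init(c_in, c_out, length(g$partitions), k)
    out <- spatial_graph_conv(x, g, p, train = FALSE)
    E <- lapply(seq_along(g$partitions), function(i)
      g$partitions[[i]] * p$mask[[i]])
    expect_equal(out, oracle_graph_conv(x, E, p$W, p$b),
                 tolerance = 1e-10)
  }

  # identity weights, single uniform partition: plain X %*% Anorm
  g <- build_skeleton_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)),
                            strategy = "uniform")
  p <- list(W = list(diag(1, 2)), mask = list(matrix(1, 4, 4)),
            b = c(0, 0))
  x <- rand_fmap(2, 2, 5, 4)
  out <- spatial_graph_conv(x, g, p, train = FALSE)
  expect_equal(out, oracle_joint_mix(x, normalize_adjacency(g)),
               tolerance = 1e-12)

  # zero input with mu = sigma = 0 noise stays zero
  p$noise <- noise_config(0, 0)
  expect_equal(spatial_graph_conv(array(0, dim = dim(x)), g, p),
               array(0, dim = dim(x)))

  expect_error(spatial_graph_conv(rand_fmap(1, 2, 3, 5), g, p), "joint")
})

test_that("noise-perturbed graph conv is seed-deterministic", {
  set.seed(22)
  g <- build_skeleton_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  p <- gcn_init(3, 3, 2, 4)
  p$noise <- noise_config(mu = 0, sigma = 0.5)
  x <- rand_fmap(2, 3, 4, 4)
  set.seed(99); y1 <- spatial_graph_conv(x, g, p, train = TRUE)
  set.seed(99); y2 <- spatial_graph_conv(x, g, p, train = TRUE)
  expect_identical(y1, y2)
  set.seed(100); y3 <- spatial_graph_conv(x, g, p, train = TRUE)
  expect_false(identical(y1, y3))
})

test_that("squeeze is the channel mean over time x joints", {
  u <- array(7, dim = c(2, 3, 4, 5))
  expect_equal(se_squeeze(u), matrix(7, 2, 3))

  u2 <- array(c(1, 2, 3, 4), dim = c(1, 1, 2, 2))
  expect_equal(se_squeeze(u2), matrix(2.5, 1, 1))

  set.seed(23)
  for (trial in 1:30) {
    u <- rand_fmap(sample(1:3, 1), sample(1:6, 1),
                   sample(1:8, 1), sample(1:5, 1))
    d <- dim(u)
    z <- matrix(0, d[1], d[2])
    for (n in seq_len(d[1])) for (cc in seq_len(d[2]))
      z[n, cc] <- mean(u[n, cc, , ])
    expect_equal(se_squeeze(u), z, tolerance = 1e-12)
  }
})

test_that("SE recalibration matches direct formula evaluation", {
  set.seed(24)
  # zero weights: all gates sigmoid(0) = 0.5
  u <- rand_fmap(2, 4, 5, 3)
  sp0 <- list(W1 = matrix(0, 1, 4), W2 = matrix(0, 4, 1), r = 4L)
  expect_equal(se_recalibrate(u, sp0), 0.5 * u, tolerance = 1e-12)

  for (trial in 1:30) {
    c_ch <- sample(c(2, 4, 6), 1)
    r <- 2L
    u <- rand_fmap(sample(1:3, 1), c_ch, sample(2:8, 1), sample(1:5, 1))
    sp <- se_init(c_ch, r)
    out <- se_recalibrate(u, sp)
    expect_equal(out, oracle_se(u, sp$W1, sp$W2), tolerance = 1e-10)
    # gates strictly inside (0, 1): output strictly shrinks channels
    gates <- sigmoid(pmax(se_squeeze(u) %*% t(sp$W1), 0) %*% t(sp$W2))
    expect_true(all(gates > 0 & gates < 1))
  }
  expect_error(se_recalibrate(u, se_init(4, 2)), "inconsistent")
  expect_error(se_init(6, 4), "divide")
})

test_that("dilated temporal conv branches match the sliding-window oracle", {
  set.seed(25)
  for (trial in 1:20) {
    c_ch <- sample(1:4, 1)
    x <- rand_fmap(sample(1:2, 1), c_ch, sample(4:8, 1), sample(1:4, 1))
    for (dil in 1:4) {
      p <- tconv_init(c_ch, sample(1:4, 1), 3L)
      for (stride in 1:2) {
        out <- tconv_fwd(x, p, stride = stride, dilation = dil)$out
        expect_equal(out, oracle_dilated_conv(x, p$W, p$b, dil, stride),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("temporal max pooling matches its oracle", {
  set.seed(26)
  for (trial in 1:20) {
    x <- rand_fmap(sample(1:2, 1), sample(1:3, 1),
                   sample(3:8, 1), sample(1:4, 1))
    for (stride in 1:2)
      expect_equal(tmaxpool_fwd(x, 3L, stride)$out,
                   oracle_tmaxpool(x, stride), tolerance = 0)
  }
})

test_that("MTCN splits into six equal-width groups and composes branches", {
  expect_equal(mtcn_width(256), 192L)  # 32 channels per branch
  expect_equal(mtcn_width(256) %/% 6L, 32L)

  set.seed(27)
  c_ch <- 12L
  mp <- mtcn_init(c_ch)
  g <- mp$c_mid %/% 6L
  x <- rand_fmap(2, c_ch, 7, 3)

  # stride 1 preserves T
  expect_equal(dim(mtcn(x, mp, 1L))[3], 7)
  expect_equal(dim(mtcn(x, mp, 2L))[3], 4)

  # manual composition from the primitives
  entry <- chan_mix_fwd(x, mp$entry$W, mp$entry$b)$out
  entry[entry < 0] <- 0
  grp <- function(i) entry[, ((i - 1) * g + 1):(i * g), , , drop = FALSE]
  pieces <- list(
    chan_mix_fwd(grp(1), mp$conv1$W, mp$conv1$b)$out,
    oracle_tmaxpool(grp(2), 1L),
    oracle_dilated_conv(grp(3), mp$dil[[1]]$W, mp$dil[[1]]$b, 1L, 1L),
    oracle_dilated_conv(grp(4), mp$dil[[2]]$W, mp$dil[[2]]$b, 2L, 1L),
    oracle_dilated_conv(grp(5), mp$dil[[3]]$W, mp$dil[[3]]$b, 3L, 1L),
    oracle_dilated_conv(grp(6), mp$dil[[4]]$W, mp$dil[[4]]$b, 4L, 1L))
  cc <- array(0, dim = c(2, mp$c_mid, 7, 3))
  at <- 0
  for (p in pieces) {
    cc[, (at + 1):(at + dim(p)[2]), , ] <- p
    at <- at + dim(p)[2]
  }
  manual <- chan_mix_fwd(cc, mp$exit$W, mp$exit$b)$out
  expect_equal(mtcn(x, mp, 1L), manual, tolerance = 1e-10)

  bad <- mp; bad$c_mid <- 10L
  expect_error(mtcn(x, bad), "divisible by 6")
})

test_that("a block equals the explicit composition of its stages", {
  set.seed(28)
  g <- build_skeleton_graph(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  cfg <- model_config(channels = c(12, 12), num_classes = 2,
                      noise_on = FALSE, se_ratio = 4)
  m <- build_model(g, cfg)
  x <- rand_fmap(2, 12, 6, 5)  # feed block 2 (identity residual)
  bp <- m$params$blocks[[2]]
  bb <- m$buffers$blocks[[2]]
  out <- stgcn_block(x, g, bp, bb, cfg, train = FALSE)

  h <- gcn_fwd(x, bp$gcn, g$partitions, NULL)$out
  h <- bn_fwd(h, bp$bn1, bb$bn1, train = FALSE)$out
  h[h < 0] <- 0
  h <- se_recalibrate(h, bp$se)
  h <- mtcn(h, bp$tcn, 1L)
  h <- bn_fwd(h, bp$bn2, bb$bn2, train = FALSE)$out
  manual <- h + x
  manual[manual < 0] <- 0
  expect_equal(out, manual, tolerance = 1e-12)

  # stride-1 block conserves (T, V)
  expect_equal(dim(out)[3:4], dim(x)[3:4])
})

test_that("hand-written gradients agree with finite differences", {
  set.seed(29)
  g <- build_skeleton_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  cfg <- model_config(channels = c(8, 8), strides = c(1, 2),
                      num_classes = 3, noise_on = FALSE)
  m <- build_model(g, cfg)
  x <- array(rnorm(3 * 3 * 6 * 4), dim = c(3, 3, 6, 4, 1))
  y <- c(1L, 2L, 3L)
  loss_of <- function(model) {
    fw <- model_fwd(model, x, train = TRUE)
    softmax_xent(fw$logits, y)$loss
  }
  fw <- model_fwd(m, x, train = TRUE)
  sx <- softmax_xent(fw$logits, y)
  gr <- model_bwd(m, fw$cache, sx$dlogits)

  leaves <- list(
    list(get = function(mo) mo$params$head$W,
         set = function(mo, v) { mo$params$head$W <- v; mo },
         g = gr$head$W),
    list(get = function(mo) mo$params$blocks[[1]]$gcn$W[[2]],
         set = function(mo, v) { mo$params$blocks[[1]]$gcn$W[[2]] <- v; mo },
         g = gr$blocks[[1]]$gcn$W[[2]]),
    list(get = function(mo) mo$params$blocks[[1]]$gcn$mask[[1]],
         set = function(mo, v) { mo$params$blocks[[1]]$gcn$mask[[1]] <- v; mo },
         g = gr$blocks[[1]]$gcn$mask[[1]]),
    list(get = function(mo) mo$params$blocks[[1]]$se$W2,
         set = function(mo, v) { mo$params$blocks[[1]]$se$W2 <- v; mo },
         g = gr$blocks[[1]]$se$W2),
    list(get = function(mo) mo$params$blocks[[2]]$tcn$dil[[4]]$W,
         set = function(mo, v) { mo$params$blocks[[2]]$tcn$dil[[4]]$W <- v; mo },
         g = gr$blocks[[2]]$tcn$dil[[4]]$W),
    list(get = function(mo) mo$params$blocks[[2]]$res$W,
         set = function(mo, v) { mo$params$blocks[[2]]$res$W <- v; mo },
         g = gr$blocks[[2]]$res$W),
    list(get = function(mo) mo$params$blocks[[1]]$bn1$gamma,
         set = function(mo, v) { mo$params$blocks[[1]]$bn1$gamma <- v; mo },
         g = gr$blocks[[1]]$bn1$gamma),
    list(get = function(mo) mo$params$data_bn$beta,
         set = function(mo, v) { mo$params$data_bn$beta <- v; mo },
         g = gr$data_bn$beta))

  eps <- 1e-5
  for (leaf in leaves) {
    p0 <- leaf$get(m)
    for (i in sample(length(p0), min(3, length(p0)))) {
      pp <- p0; pp[i] <- pp[i] + eps
      pm <- p0; pm[i] <- pm[i] - eps
      num <- (loss_of(leaf$set(m, pp)) - loss_of(leaf$set(m, pm))) /
        (2 * eps)
      expect_equal(leaf$g[i], num, tolerance = 1e-4)
    }
  }
})
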