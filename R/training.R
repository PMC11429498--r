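# Supervised training of the encoder + softmax classifier on normal
# behavior clips: SGD with momentum, cross-entropy loss, scale/translate
# augmentation, and top-k evaluation.

#' Training configuration
#'
#' Defaults follow the standard recipe: SGD with an initial learning rate
#' of 0.1, batch size 64, 100 epochs, momentum 0.9, weight decay 1e-4,
#' step decay x0.1 at epochs 40 and 80, and per-clip augmentation drawing
#' a scale factor from [0.97, 1.03] and a translation from [-5, 5] pixels.
#'
#' @param learning_rate Initial SGD learning rate.
#' @param batch_size Clips per gradient step.
#' @param epochs Training epochs.
#' @param momentum Momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param scale_range Augmentation scale factor range.
#' @param shift_range_px Augmentation translation range in pixels;
#'   converted to normalized units with the clip's stored frame scale.
#' @param lr_decay_epochs Epochs at which the learning rate is multiplied
#'   by `lr_decay_factor`.
#' @param lr_decay_factor Multiplicative step decay.
#' @param seed Optional integer seed applied at the start of training.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, batch_size = 64L,
                         epochs = 100L, momentum = 0.9,
                         weight_decay = 1e-4,
                         scale_range = c(0.97, 1.03),
                         shift_range_px = c(-5, 5),
                         lr_decay_epochs = c(40L, 80L),
                         lr_decay_factor = 0.1,
                         seed = NULL) {
  stopifnot(scale_range[1L] <= scale_range[2L],
            shift_range_px[1L] <= shift_range_px[2L],
            batch_size >= 1L, epochs >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 momentum = momentum, weight_decay = weight_decay,
                 scale_range = scale_range,
                 shift_range_px = shift_range_px,
                 lr_decay_epochs = as.integer(lr_decay_epochs),
                 lr_decay_factor = lr_decay_factor,
                 seed = seed),
            class = "train_config")
}

#' Scale/translate augmentation of a skeleton clip
#'
#' Multiplies the x and y channels by one scalar drawn uniformly from
#' `cfg$scale_range` and shifts them by a per-clip (dx, dy) drawn
#' uniformly from `cfg$shift_range_px` pixels.  For normalized clips the
#' pixel shift is converted to normalized units by dividing by half the
#' larger frame dimension.  The confidence channel is untouched.
#'
#' @param clip A `skeleton_sequence`.
#' @param cfg A [train_config()].
#' @return The augmented `skeleton_sequence`.
#' @export
augment <- function(clip, cfg) {
  s <- stats::runif(1L, cfg$scale_range[1L], cfg$scale_range[2L])
  dx <- stats::runif(1L, cfg$shift_range_px[1L], cfg$shift_range_px[2L])
  dy <- stats::runif(1L, cfg$shift_range_px[1L], cfg$shift_range_px[2L])
  if (isTRUE(clip$normalized)) {
    half <- if (!is.null(clip$frame_size)) max(clip$frame_size) / 2
            else 1
    dx <- dx / half
    dy <- dy / half
  }
  clip$data[, 1L, , , ] <- clip$data[, 1L, , , ] * s + dx
  clip$data[, 2L, , , ] <- clip$data[, 2L, , , ] * s + dy
  clip
}

# batch version operating on a stacked (n, C, T, V, M) tensor; one draw
# triple per clip, same draw semantics as augment()
augment_tensor <- function(tensor, cfg, frame_half, normalized) {
  n <- dim(tensor)[1L]
  for (i in seq_len(n)) {
    s <- stats::runif(1L, cfg$scale_range[1L], cfg$scale_range[2L])
    dx <- stats::runif(1L, cfg$shift_range_px[1L], cfg$shift_range_px[2L])
    dy <- stats::runif(1L, cfg$shift_range_px[1L], cfg$shift_range_px[2L])
    if (normalized) {
      dx <- dx / frame_half
      dy <- dy / frame_half
    }
    tensor[i, 1L, , , ] <- tensor[i, 1L, , , ] * s + dx
    tensor[i, 2L, , , ] <- tensor[i, 2L, , , ] * s + dy
  }
  tensor
}

# ---- SGD with momentum over nested parameter lists -------------------

sgd_update <- function(params, grads, vel, lr, momentum, wd) {
  if (is.numeric(grads)) {
    g <- grads + wd * params
    v <- if (is.null(vel)) array(0, dim = dim(g) %||% length(g)) else vel
    v <- momentum * v - lr * g
    return(list(p = params + v, v = v))
  }
  if (is.null(vel)) vel <- vector("list", length(grads))
  for (nm in seq_along(grads)) {
    key <- if (!is.null(names(grads))) names(grads)[nm] else nm
    upd <- sgd_update(params[[key]], grads[[nm]], vel[[nm]],
                      lr, momentum, wd)
    params[[key]] <- upd$p
    vel[[nm]] <- upd$v
  }
  list(p = params, v = vel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the encoder and classifier
#'
#' Minimizes softmax cross-entropy with SGD at the settings in `cfg`.
#' Augmentation is applied to training batches only; when the Gaussian
#' adjacency perturbation is enabled a fresh noise matrix is drawn for
#' every layer on every batch.  Deterministic for a fixed `cfg$seed`.
#'
#' @param model An untrained `stgcn_model`.
#' @param train_ds Labeled `clip_dataset`.
#' @param eval_ds Optional labeled `clip_dataset` evaluated each epoch.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch?
#' @return List with elements `model` (trained) and `history` (a tibble
#'   of class `train_history` with per-epoch loss and accuracies).
#' @export
train_model <- function(model, train_ds, eval_ds = NULL,
                        cfg = train_config(), verbose = FALSE) {
  if (is.null(train_ds$labels))
    stop("training requires a labeled dataset", call. = FALSE)
  n <- length(train_ds$clips)
  if (n == 0L) stop("training dataset is empty", call. = FALSE)
  labels <- as.integer(train_ds$labels)
  if (length(unique(labels)) < 2L)
    stop("training requires at least 2 classes", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tensor <- stack_clips(train_ds)
  first <- train_ds$clips[[1L]]
  frame_half <- if (!is.null(first$frame_size)) max(first$frame_size) / 2
                else 1
  normalized <- isTRUE(first$normalized)
  eval_tensor <- if (!is.null(eval_ds)) stack_clips(eval_ds)
  vel <- NULL
  hist <- vector("list", cfg$epochs)
  n_classes <- model$config$num_classes
  k5 <- min(5L, n_classes)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$learning_rate *
      cfg$lr_decay_factor ^ sum(epoch > cfg$lr_decay_epochs)
    ord <- sample.int(n)
    losses <- c()
    correct <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- tensor[idx, , , , , drop = FALSE]
      xb <- augment_tensor(xb, cfg, frame_half, normalized)
      yb <- labels[idx]
      fw <- model_fwd(model, xb, train = TRUE)
      model <- fw$model
      sx <- softmax_xent(fw$logits, yb)
      losses <- c(losses, sx$loss)
      correct <- correct +
        sum(max.col(sx$probs, ties.method = "first") == yb)
      grads <- model_bwd(model, fw$cache, sx$dlogits)
      upd <- sgd_update(model$params, grads, vel, lr, cfg$momentum,
                        cfg$weight_decay)
      model$params <- upd$p
      vel <- upd$v
    }
    eval_top1 <- NA_real_
    eval_top5 <- NA_real_
    if (!is.null(eval_ds) && !is.null(eval_ds$labels)) {
      ev <- model_fwd(model, eval_tensor, train = FALSE)
      probs <- softmax_rows(sweep(ev$embedding %*% model$params$head$W,
                                  2L, model$params$head$b, "+"))
      eval_top1 <- topk_accuracy(probs, eval_ds$labels, 1L)
      eval_top5 <- topk_accuracy(probs, eval_ds$labels, k5)
    }
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, loss = mean(losses),
      train_top1 = correct / n,
      eval_top1 = eval_top1, eval_top5 = eval_top5)
    if (verbose)
      message(sprintf("epoch %3d  lr %.4g  loss %.4f  train top-1 %.3f",
                      epoch, lr, mean(losses), correct / n))
  }
  # batch-norm calibration: set the running statistics to the exact
  # activation statistics of the clean (unaugmented, noise-free)
  # training set, so evaluation-mode forwards match what was learned
  model <- calibrate_bn(model, tensor)
  history <- dplyr::bind_rows(hist)
  class(history) <- c("train_history", class(history))
  attr(history, "config") <- cfg
  list(model = model, history = history)
}

#' Recalibrate batch-norm running statistics
#'
#' Runs one training-mode forward pass over `tensor` (a stacked clip
#' tensor or `clip_dataset`) with augmentation and adjacency noise
#' disabled and the buffer momentum set to 1, so every batch-norm layer
#' stores the exact activation statistics of that data.  Called
#' automatically at the end of [train_model()].
#'
#' @param model An `stgcn_model`.
#' @param tensor A rank-5 tensor or `clip_dataset`.
#' @return The model with updated buffers.
#' @export
calibrate_bn <- function(model, tensor) {
  tensor <- clip_tensor(tensor)
  fw <- model_fwd(model, tensor, train = TRUE, bn_momentum = 1,
                  use_noise = FALSE)
  fw$model
}

#' Top-k classification accuracy
#'
#' Fraction of clips whose true label is among the k highest-probability
#' classes.  Ties are broken by class index: among equal probabilities
#' the lower class index is ranked first.
#'
#' @param probs Matrix of class probabilities, one row per clip.
#' @param labels Integer true classes (1-based).
#' @param k Number of top predictions considered.
#' @return Fraction in [0, 1].
#' @export
topk_accuracy <- function(probs, labels, k = 1L) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (nrow(probs) != length(labels))
    stop("probs and labels disagree in length", call. = FALSE)
  stopifnot(k >= 1L, k <= ncol(probs))
  hits <- vapply(seq_len(nrow(probs)), function(i) {
    ranked <- order(probs[i, ], decreasing = TRUE)  # stable: low index first
    labels[i] %in% ranked[seq_len(k)]
  }, logical(1L))
  mean(hits)
}
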