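# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the precision-recall curve of a PR metrics object
#'
#' @param x A `pr_metrics` from [average_precision()].
#' @param ... Unused.
#' @return Tibble with columns `threshold`, `precision`, `recall`.
#' @export
tidy.pr_metrics <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds,
                 precision = x$precision,
                 recall = x$recall)
}

#' @rdname tidy.pr_metrics
#' @export
glance.pr_metrics <- function(x, ...) {
  tibble::tibble(ap = x$ap, tp = x$tp, fp = x$fp, fn = x$fn,
                 n_thresholds = length(x$thresholds))
}

#' One-row summary of an anomaly report
#'
#' @param x An `anomaly_report` from [detect_abnormal()].
#' @param ... Unused.
#' @return Tibble with cluster/flag counts and the detector parameters.
#' @export
glance.anomaly_report <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(n_clips = nrow(x),
                 n_abnormal = sum(x$is_abnormal),
                 n_normal = sum(!x$is_abnormal),
                 num_clusters = p$num_clusters,
                 pca_dims = p$pca_dims, eps = p$eps,
                 min_samples = p$min_samples)
}

#' Explained variance of a fitted PCA reduction
#'
#' @param x A `pca_reduction` from [pca_fit_reduce()].
#' @param ... Unused.
#' @return Tibble with `component`, `explained_variance_ratio`,
#'   `cumulative`.
#' @export
tidy.pca_reduction <- function(x, ...) {
  evr <- x$explained_variance_ratio
  tibble::tibble(component = seq_along(evr),
                 explained_variance_ratio = evr,
                 cumulative = cumsum(evr))
}

#' One-row summary of a fitted encoder model
#'
#' @param x An `stgcn_model`.
#' @param ... Unused.
#' @return Tibble with block count, parameter count, embedding dim and
#'   the enhancement toggles.
#' @export
glance.stgcn_model <- function(x, ...) {
  tibble::tibble(n_blocks = length(x$config$channels),
                 n_parameters = count_params(x$params),
                 embedding_dim = x$embedding_dim,
                 num_classes = x$config$num_classes,
                 noise_on = x$config$noise_on,
                 se_on = x$config$se_on,
                 mtcn_on = x$config$mtcn_on)
}

#' Plot training history
#'
#' Loss and accuracy traces per epoch.
#'
#' @param object A `train_history` tibble from [train_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.train_history <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = df$epoch, value = df$loss, metric = "loss"),
    tibble::tibble(epoch = df$epoch, value = df$train_top1,
                   metric = "train top-1"),
    if (!all(is.na(df$eval_top1)))
      tibble::tibble(epoch = df$epoch, value = df$eval_top1,
                     metric = "eval top-1"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an anomaly report in reduced space
#'
#' Scatter of the first two principal components, colored by cluster,
#' with flagged anomalies drawn in black.
#'
#' @param object An `anomaly_report` from [detect_abnormal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anomaly_report <- function(object, ...) {
  pts <- attr(object, "reduced")
  df <- tibble::tibble(
    pc1 = pts[, 1L],
    pc2 = if (ncol(pts) >= 2L) pts[, 2L] else 0,
    cluster = factor(object$cluster_id),
    abnormal = object$is_abnormal)
  ggplot2::ggplot(df[!df$abnormal, ],
                  ggplot2::aes(x = .data$pc1, y = .data$pc2,
                               color = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_point(data = df[df$abnormal, ],
                        color = "black", shape = 17, size = 2.5) +
    ggplot2::labs(x = "PC 1", y = "PC 2", color = "cluster",
                  title = "Embedding clusters (black = flagged abnormal)") +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param object A `pr_metrics` from [average_precision()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_metrics <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall,
                                   y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("AP = %.4f", object$ap)) +
    ggplot2::theme_minimal()
}
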