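# Reading, normalizing, segmenting and persisting keypoint trajectories.
#
# The canonical container is a rank-5 tensor indexed (N, C, T, V, M):
# clip, channel (x, y, conf), frame, joint, animal.  M = 1 throughout the
# single-animal pipeline.

#' Skeleton sequence container
#'
#' Wraps a rank-5 numeric tensor of keypoint trajectories with its channel
#' and joint labels.  Channels are always `x`, `y`, `conf` in that order;
#' the confidence channel must lie in [0, 1].
#'
#' @param data Numeric array with dim (N, C, T, V, M), C = 3.
#' @param keypoint_names Character vector of V joint labels.
#' @param fps Optional frames/second metadata.
#' @param frame_size Optional c(width, height) in pixels of the source
#'   video; required later to convert pixel-unit augmentation shifts after
#'   coordinate normalization.
#' @param normalized Logical; have coordinates been mapped to [-1, 1]?
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(data, keypoint_names, fps = NULL,
                              frame_size = NULL, normalized = FALSE) {
  d <- dim(data)
  if (length(d) != 5L)
    stop("skeleton data must be a rank-5 (N, C, T, V, M) array",
         call. = FALSE)
  if (d[2L] != 3L)
    stop("expected 3 channels (x, y, conf); got ", d[2L], call. = FALSE)
  if (d[4L] != length(keypoint_names))
    stop("joint dimension (", d[4L], ") does not match keypoint_names (",
         length(keypoint_names), ")", call. = FALSE)
  conf <- data[, 3L, , , , drop = FALSE]
  if (any(conf < -1e-9 | conf > 1 + 1e-9, na.rm = TRUE))
    stop("confidence channel must lie in [0, 1]", call. = FALSE)
  structure(
    list(data = data,
         channel_names = c("x", "y", "conf"),
         keypoint_names = as.character(keypoint_names),
         fps = fps, frame_size = frame_size, normalized = normalized),
    class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  d <- dim(x$data)
  cat("<skeleton_sequence> N=", d[1L], " C=", d[2L], " T=", d[3L],
      " V=", d[4L], " M=", d[5L],
      if (isTRUE(x$normalized)) " (normalized)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.skeleton_sequence <- function(x) dim(x$data)

#' Read a DeepLabCut-style keypoint CSV
#'
#' Parses the three-row DeepLabCut header dialect (scorer / bodyparts /
#' coords) where each body part contributes `x`, `y`, `likelihood`
#' columns, and returns a single-clip, single-animal skeleton sequence
#' with likelihood mapped to the confidence channel.
#'
#' @param path CSV file path.
#' @param keypoint_names Joints to extract, in the desired order; defaults
#'   to the body parts in file order.
#' @param fps,frame_size Optional metadata attached to the result.
#' @return A `skeleton_sequence` with N = 1, M = 1.
#' @export
read_dlc_csv <- function(path, keypoint_names = NULL, fps = NULL,
                         frame_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("not a DeepLabCut CSV: fewer than 3 header rows", call. = FALSE)
  split_row <- function(s) {
    out <- strsplit(s, ",", fixed = TRUE)[[1L]]
    trimws(out)
  }
  bodyparts <- split_row(lines[2L])
  coords <- split_row(lines[3L])
  has_index <- identical(tolower(coords[1L]), "coords") ||
    identical(coords[1L], "")
  col0 <- if (has_index) 1L else 0L
  bodyparts <- bodyparts[-seq_len(col0)]
  coords <- coords[-seq_len(col0)]
  if (length(bodyparts) != length(coords))
    stop("malformed header: bodyparts/coords rows differ in length",
         call. = FALSE)
  file_parts <- unique(bodyparts)
  if (is.null(keypoint_names)) keypoint_names <- file_parts
  col_of <- function(part, coord) {
    hit <- which(bodyparts == part & coords == coord)
    if (length(hit) != 1L)
      stop("missing or duplicated column for joint '", part,
           "' coordinate '", coord, "'", call. = FALSE)
    hit + col0
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  t_len <- length(body)
  v <- length(keypoint_names)
  out <- array(0, dim = c(1L, 3L, t_len, v, 1L))
  cells <- lapply(body, split_row)
  ncol_expected <- length(bodyparts) + col0
  for (t in seq_len(t_len)) {
    row <- cells[[t]]
    if (length(row) < ncol_expected)
      stop("row ", t, ": expected ", ncol_expected, " cells, got ",
           length(row), call. = FALSE)
  }
  coord_names <- c("x", "y", "likelihood")
  for (j in seq_len(v)) {
    for (cidx in 1:3) {
      col <- col_of(keypoint_names[j], coord_names[cidx])
      vals <- vapply(cells, `[[`, "", col)
      num <- suppressWarnings(as.numeric(vals))
      bad <- which(is.na(num) & !(vals %in% c("NA", "NaN")))
      if (length(bad) > 0)
        stop("non-numeric cell '", vals[bad[1L]], "' at data row ",
             bad[1L], ", joint '", keypoint_names[j], "'", call. = FALSE)
      out[1L, cidx, , j, 1L] <- num
    }
  }
  skeleton_sequence(out, keypoint_names, fps = fps, frame_size = frame_size)
}

#' Write a skeleton sequence as a DeepLabCut-style CSV
#'
#' @param seq A `skeleton_sequence` with N = 1, M = 1.
#' @param path Output file path.
#' @param scorer Scorer tag placed in the first header row.
#' @export
write_dlc_csv <- function(seq, path, scorer = "stgcnad") {
  d <- dim(seq$data)
  stopifnot(d[1L] == 1L, d[5L] == 1L)
  v <- d[4L]
  header1 <- paste(c("scorer", rep(scorer, 3L * v)), collapse = ",")
  header2 <- paste(c("bodyparts", rep(seq$keypoint_names, each = 3L)),
                   collapse = ",")
  header3 <- paste(c("coords", rep(c("x", "y", "likelihood"), v)),
                   collapse = ",")
  rows <- vapply(seq_len(d[3L]), function(t) {
    vals <- as.vector(vapply(seq_len(v), function(j)
      c(seq$data[1L, 1L, t, j, 1L], seq$data[1L, 2L, t, j, 1L],
        seq$data[1L, 3L, t, j, 1L]), numeric(3L)))
    paste(c(t - 1L, format(vals, digits = 17, trim = TRUE,
                           scientific = FALSE)), collapse = ",")
  }, character(1L))
  writeLines(c(header1, header2, header3, rows), path)
  invisible(path)
}

#' Normalize pixel coordinates to [-1, 1]
#'
#' Centers x and y on the frame midpoint and divides both by half the
#' larger frame dimension, preserving aspect ratio (one shared scale).
#' The confidence channel is untouched.  The frame size is stored on the
#' result so pixel-unit augmentation can be converted later.
#'
#' @param seq A `skeleton_sequence`.
#' @param frame_width,frame_height Frame dimensions in pixels (> 0).
#' @return The normalized `skeleton_sequence`.
#' @export
normalize_coordinates <- function(seq, frame_width, frame_height) {
  if (frame_width <= 0 || frame_height <= 0)
    stop("frame dimensions must be positive", call. = FALSE)
  scale <- max(frame_width, frame_height) / 2
  seq$data[, 1L, , , ] <- (seq$data[, 1L, , , ] - frame_width / 2) / scale
  seq$data[, 2L, , , ] <- (seq$data[, 2L, , , ] - frame_height / 2) / scale
  seq$frame_size <- c(frame_width, frame_height)
  seq$normalized <- TRUE
  seq
}

#' Canonicalize body pose within a clip
#'
#' View normalization: translates every frame so that the first-frame
#' body center (mean over the axis joints) is the origin, and rotates
#' all frames so that the first-frame body axis points along +x.  This
#' removes the arbitrary arena position and heading of a clip while
#' preserving all within-clip motion, which is what the behavior
#' classes differ in.
#'
#' The body axis is the principal direction of the first-frame
#' positions of `axis_joints` (by default the six spine-line joints),
#' oriented from `root` towards `head_joint`.  Estimating the axis from
#' many roughly collinear joints instead of a single pair keeps the
#' heading error small under observation jitter — the error would
#' otherwise be amplified by long trajectories like straight-line
#' locomotion.  The confidence channel is untouched.
#'
#' @param seq A `skeleton_sequence`.
#' @param root Tail-side reference joint (default `"spine_mid"`).
#' @param head_joint Head-side reference joint orienting the axis sign
#'   (default `"nose"`).
#' @param axis_joints Joints whose first-frame positions define the
#'   axis; defaults to the spine line, intersected with the available
#'   keypoints (at least 2 required).
#' @return The canonicalized `skeleton_sequence`.
#' @export
canonicalize_pose <- function(seq, root = "spine_mid",
                              head_joint = "nose",
                              axis_joints = c("nose", "head", "neck",
                                              "spine_mid", "tail_base",
                                              "tail_tip")) {
  kp <- seq$keypoint_names
  ri <- match(root, kp)
  hi <- match(head_joint, kp)
  ax <- match(intersect(axis_joints, kp), kp)
  if (is.na(ri) || is.na(hi) || length(ax) < 2L)
    stop("root/head/axis joints not found among keypoints",
         call. = FALSE)
  d <- dim(seq$data)
  for (n in seq_len(d[1L])) for (m in seq_len(d[5L])) {
    x <- seq$data[n, 1L, , , m]
    y <- seq$data[n, 2L, , , m]
    if (d[3L] == 1L) { x <- matrix(x, 1L); y <- matrix(y, 1L) }
    pts <- cbind(x[1L, ax], y[1L, ax])
    ctr <- colMeans(pts)
    sw <- crossprod(sweep(pts, 2L, ctr))
    axis <- eigen(sw, symmetric = TRUE)$vectors[, 1L]
    # orient from the tail-side root towards the head
    fwd <- c(x[1L, hi] - x[1L, ri], y[1L, hi] - y[1L, ri])
    if (sum(axis * fwd) < 0) axis <- -axis
    th <- atan2(axis[2L], axis[1L])
    xs <- x - ctr[1L]; ys <- y - ctr[2L]
    seq$data[n, 1L, , , m] <- cos(th) * xs + sin(th) * ys
    seq$data[n, 2L, , , m] <- -sin(th) * xs + cos(th) * ys
  }
  seq
}

#' Segment a sequence into fixed-length clips
#'
#' Non-overlapping consecutive windows of exactly `clip_len` frames;
#' any trailing remainder shorter than `clip_len` is dropped.
#'
#' @param seq A `skeleton_sequence` (N = 1).
#' @param clip_len Frames per clip (>= 1); default 50.
#' @return A `clip_dataset`.
#' @export
segment_clips <- function(seq, clip_len = 50L) {
  stopifnot(clip_len >= 1L)
  d <- dim(seq$data)
  n_clips <- d[3L] %/% clip_len
  clips <- vector("list", n_clips)
  for (i in seq_len(n_clips)) {
    idx <- ((i - 1L) * clip_len + 1L):(i * clip_len)
    clip <- seq
    clip$data <- seq$data[, , idx, , , drop = FALSE]
    clips[[i]] <- clip
  }
  clip_dataset(clips)
}

#' Clip dataset container
#'
#' A list of equally shaped single-clip skeleton sequences with optional
#' integer class labels.
#'
#' @param clips List of `skeleton_sequence` objects, each with N = 1; all
#'   must share (T, V, M).
#' @param labels Optional integer vector, one 1-based class per clip.
#' @param label_names Optional ordered class labels.
#' @param split_tag Optional `"train"`/`"test"` marker.
#' @return An object of class `clip_dataset`.
#' @export
clip_dataset <- function(clips, labels = NULL, label_names = NULL,
                         split_tag = NULL) {
  if (length(clips) > 0) {
    dims <- vapply(clips, function(cl) dim(cl$data), integer(5L))
    if (any(dims[1L, ] != 1L))
      stop("every clip must have N = 1", call. = FALSE)
    if (length(unique(apply(dims[2:5, , drop = FALSE], 2L, paste,
                            collapse = "x"))) != 1L)
      stop("all clips must share (C, T, V, M)", call. = FALSE)
  }
  if (!is.null(labels)) {
    if (length(labels) != length(clips))
      stop("labels must have one entry per clip", call. = FALSE)
    labels <- as.integer(labels)
    if (!is.null(label_names) &&
        any(labels < 1L | labels > length(label_names), na.rm = TRUE))
      stop("labels reference classes outside label_names", call. = FALSE)
  }
  structure(list(clips = clips, labels = labels,
                 label_names = label_names, split_tag = split_tag),
            class = "clip_dataset")
}

#' @export
length.clip_dataset <- function(x) length(x$clips)

#' @export
print.clip_dataset <- function(x, ...) {
  cat("<clip_dataset> ", length(x$clips), " clips",
      if (!is.null(x$labels))
        paste0(", ", length(unique(x$labels)), " classes"),
      if (!is.null(x$split_tag)) paste0(" [", x$split_tag, "]"),
      "\n", sep = "")
  invisible(x)
}

# stack a clip_dataset into one (n, C, T, V, M) tensor
stack_clips <- function(ds) {
  n <- length(ds$clips)
  if (n == 0L) return(array(0, dim = c(0L, 3L, 0L, 0L, 1L)))
  d <- dim(ds$clips[[1L]]$data)
  out <- array(0, dim = c(n, d[2L], d[3L], d[4L], d[5L]))
  for (i in seq_len(n)) out[i, , , , ] <- ds$clips[[i]]$data
  out
}

unstack_clips <- function(tensor, keypoint_names, fps = NULL,
                          frame_size = NULL, normalized = FALSE) {
  n <- dim(tensor)[1L]
  lapply(seq_len(n), function(i) {
    skeleton_sequence(tensor[i, , , , , drop = FALSE], keypoint_names,
                      fps = fps, frame_size = frame_size,
                      normalized = normalized)
  })
}

#' Persist / load a clip dataset archive
#'
#' A single-file archive holding the stacked (n, C, T, V, M) tensor, the
#' label vector and a metadata block (joint names, class names, frame
#' size, split tag).  The round trip is lossless and byte-stable: writing
#' the same dataset twice yields identical files.
#'
#' @param ds A `clip_dataset`.
#' @param path Archive file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset`
#'   returns the restored `clip_dataset`.
#' @export
write_dataset <- function(ds, path) {
  first <- if (length(ds$clips) > 0) ds$clips[[1L]] else NULL
  payload <- list(
    format = "stgcnad_clip_dataset",
    version = 1L,
    tensor = stack_clips(ds),
    labels = ds$labels,
    meta = list(
      keypoint_names = if (!is.null(first)) first$keypoint_names,
      label_names = ds$label_names,
      split_tag = ds$split_tag,
      fps = if (!is.null(first)) first$fps,
      frame_size = if (!is.null(first)) first$frame_size,
      normalized = if (!is.null(first)) first$normalized else FALSE))
  saveRDS(payload, path, version = 3L, compress = "gzip")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or unreadable dataset archive: ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(payload) ||
      !identical(payload$format, "stgcnad_clip_dataset"))
    stop("not a clip dataset archive", call. = FALSE)
  m <- payload$meta
  clips <- if (dim(payload$tensor)[1L] > 0)
    unstack_clips(payload$tensor, m$keypoint_names, fps = m$fps,
                  frame_size = m$frame_size,
                  normalized = isTRUE(m$normalized))
  else list()
  clip_dataset(clips, labels = payload$labels,
               label_names = m$label_names, split_tag = m$split_tag)
}
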