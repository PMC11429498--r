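# Kinematic simulator of top-view mouse skeleton clips.
#
# Four normal behavior classes — movement (straight-line locomotion),
# head turning (static body, large head rotation about the neck),
# standing (rearing: front of the body compresses toward the neck with a
# static centroid), turning (the heading of the whole spine changes over
# the clip) — plus parameterised anomaly families used only for testing
# the semi-supervised detector.  The skeleton template proportions are
# package constants (a plausible top-view mouse); all kinematic rates
# are configurable.

NORMAL_BEHAVIORS <- c("movement", "head_turning", "standing", "turning")
ANOMALY_BEHAVIORS <- c("anomaly_freeze", "anomaly_jump", "anomaly_limb")

# local body frame, px: +x towards the nose, origin at spine_mid
mouse_template <- function() {
  rbind(
    nose = c(60, 0), head = c(45, 0),
    L_ear = c(40, -12), R_ear = c(40, 12),
    neck = c(30, 0),
    L_forepaw = c(22, -18), R_forepaw = c(22, 18),
    spine_mid = c(0, 0),
    L_hindpaw = c(-8, -22), R_hindpaw = c(-8, 22),
    tail_base = c(-30, 0), tail_tip = c(-75, 0))
}

#' Behavior specification for the clip simulator
#'
#' @param behavior One of `"movement"`, `"head_turning"`, `"standing"`,
#'   `"turning"`, `"anomaly_freeze"`, `"anomaly_jump"`,
#'   `"anomaly_limb"`.
#' @param t_len Clip length in frames (default 50, i.e. the fixed
#'   cropping length of the pipeline).
#' @param frame_size c(width, height) of the simulated arena in pixels.
#' @param speed Centroid speed, px/frame (movement and turning).
#' @param turn_rate Heading change, rad/frame (turning).
#' @param head_amplitude Peak head rotation about the neck, rad
#'   (head turning).
#' @param rear_amplitude Fractional front-template compression
#'   (standing).
#' @param jitter_sd Gaussian observation noise per joint per frame, px.
#' @return An object of class `behavior_spec`.
#' @export
behavior_spec <- function(behavior, t_len = 50L,
                          frame_size = c(640, 480),
                          speed = 4, turn_rate = 0.04,
                          head_amplitude = 1.05, rear_amplitude = 0.4,
                          jitter_sd = 1.5) {
  behavior <- as.character(behavior)
  if (!behavior %in% c(NORMAL_BEHAVIORS, ANOMALY_BEHAVIORS))
    stop("unknown behavior tag: '", behavior, "'", call. = FALSE)
  stopifnot(t_len >= 2L, jitter_sd >= 0)
  structure(list(behavior = behavior, t_len = as.integer(t_len),
                 frame_size = frame_size, speed = speed,
                 turn_rate = turn_rate, head_amplitude = head_amplitude,
                 rear_amplitude = rear_amplitude, jitter_sd = jitter_sd),
            class = "behavior_spec")
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Generate one synthetic behavior clip
#'
#' Animates the 12-joint template skeleton according to the behavior's
#' kinematic model, adds i.i.d. Gaussian observation jitter, and draws
#' the confidence channel from a high-value Beta distribution.  Uses the
#' current R random stream.
#'
#' @param spec A [behavior_spec()].
#' @return A `skeleton_sequence` in pixel coordinates (N = 1, M = 1)
#'   with `frame_size` metadata attached.
#' @export
generate_behavior_clip <- function(spec) {
  tmpl <- mouse_template()
  v <- nrow(tmpl)
  t_len <- spec$t_len
  w <- spec$frame_size[1L]
  h <- spec$frame_size[2L]
  # start position in the central half of the arena, random base heading
  margin_x <- w / 4
  margin_y <- h / 4
  center0 <- c(stats::runif(1L, margin_x, w - margin_x),
               stats::runif(1L, margin_y, h - margin_y))
  heading0 <- stats::runif(1L, 0, 2 * pi)
  head_group <- c("nose", "head", "L_ear", "R_ear")
  front_group <- c("nose", "head", "L_ear", "R_ear",
                   "L_forepaw", "R_forepaw")
  neck <- tmpl["neck", ]
  xy <- array(0, dim = c(2L, t_len, v))
  center <- center0
  heading <- heading0
  limb_offset <- c(0, 0)
  for (t in seq_len(t_len)) {
    pts <- tmpl
    phase <- (t - 1) / max(t_len - 1, 1)
    switch(spec$behavior,
      movement = {
        center <- center0 + (t - 1) * spec$speed *
          c(cos(heading0), sin(heading0))
      },
      head_turning = {
        ang <- spec$head_amplitude * sin(2 * pi * phase)
        R <- rot2(ang)
        for (j in head_group)
          pts[j, ] <- neck + as.vector(R %*% (tmpl[j, ] - neck))
      },
      standing = {
        # rearing: the front template compresses toward the neck, with
        # a small bob; centroid static
        f <- 1 - spec$rear_amplitude * (0.8 + 0.2 * sin(2 * pi * phase))
        for (j in front_group)
          pts[j, ] <- neck + f * (tmpl[j, ] - neck)
      },
      turning = {
        heading <- heading0 + (t - 1) * spec$turn_rate
        center <- center + spec$speed * 0.4 *
          c(cos(heading), sin(heading))
      },
      anomaly_freeze = {
        # immobile with high-frequency full-body tremor
        trem <- (-1)^t * 4 + stats::rnorm(1L, sd = 2)
        pts[, 1L] <- pts[, 1L] + trem
        pts[, 2L] <- pts[, 2L] - trem
      },
      anomaly_jump = {
        # erratic heavy-tailed displacement between frames
        step <- pmin(pmax(stats::rcauchy(2L, scale = 8), -60), 60)
        center <- center + step
        center <- pmin(pmax(center, c(10, 10)), c(w - 10, h - 10))
      },
      anomaly_limb = {
        # one forepaw decouples and random-walks away from the body
        limb_offset <- limb_offset + stats::rnorm(2L, sd = 10)
        pts["L_forepaw", ] <- pts["L_forepaw", ] + limb_offset
      })
    R <- rot2(heading)
    world <- t(R %*% t(pts)) + rep(center, each = v)
    xy[, t, ] <- t(world)
  }
  if (spec$jitter_sd > 0)
    xy <- xy + stats::rnorm(length(xy), sd = spec$jitter_sd)
  conf <- stats::rbeta(t_len * v, 20, 1.5)
  data <- array(0, dim = c(1L, 3L, t_len, v, 1L))
  data[1L, 1L, , , 1L] <- xy[1L, , ]
  data[1L, 2L, , , 1L] <- xy[2L, , ]
  data[1L, 3L, , , 1L] <- conf
  skeleton_sequence(data, rownames(tmpl), fps = 30,
                    frame_size = spec$frame_size)
}

#' Synthetic dataset specification
#'
#' @param n_per_class Normal clips per behavior class.
#' @param behaviors Normal behavior tags (default all four).
#' @param anomaly_fraction Planted anomalies as a fraction of the total
#'   normal clip count (must be < 1); ignored when `n_anomalies` given.
#' @param n_anomalies Explicit anomaly count (overrides the fraction).
#' @param split_ratio Train fraction of the stratified split
#'   (default 0.8).
#' @param t_len Clip length in frames.
#' @param jitter_sd Observation noise, px.
#' @param canonicalize Apply [canonicalize_pose()] after coordinate
#'   normalization (default TRUE), removing each clip's arbitrary arena
#'   position and heading before training.
#' @param seed Optional seed making the dataset fully reproducible.
#' @return An object of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_per_class = 25L,
                                   behaviors = NORMAL_BEHAVIORS,
                                   anomaly_fraction = 0.1,
                                   n_anomalies = NULL,
                                   split_ratio = 0.8,
                                   t_len = 50L, jitter_sd = 1.5,
                                   canonicalize = TRUE,
                                   seed = NULL) {
  if (anomaly_fraction >= 1)
    stop("anomaly_fraction must be < 1", call. = FALSE)
  stopifnot(anomaly_fraction >= 0, split_ratio > 0, split_ratio < 1,
            n_per_class >= 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 behaviors = behaviors,
                 anomaly_fraction = anomaly_fraction,
                 n_anomalies = n_anomalies,
                 split_ratio = split_ratio, t_len = as.integer(t_len),
                 jitter_sd = jitter_sd, canonicalize = canonicalize,
                 seed = seed),
            class = "synthetic_dataset_spec")
}

#' Generate a labeled train/test dataset with planted anomalies
#'
#' Normal clips are split 8:2 (stratified by class, train count rounded
#' per class); anomalies are planted in the test split only, matching
#' the semi-supervised protocol in which training sees normal behavior
#' exclusively.  Coordinates are normalized to [-1, 1].
#'
#' @param spec A [synthetic_dataset_spec()].
#' @return List with `train` (labeled `clip_dataset`), `test` (labeled
#'   `clip_dataset`; anomalies carry label `NA`), and `truth` (logical,
#'   one flag per test clip: `TRUE` = planted anomaly).
#' @export
generate_dataset <- function(spec) {
  total_normal <- spec$n_per_class * length(spec$behaviors)
  if (total_normal < 10L)
    stop("need a total of at least 10 normal clips", call. = FALSE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n_anom <- if (!is.null(spec$n_anomalies)) as.integer(spec$n_anomalies)
            else as.integer(round(spec$anomaly_fraction * total_normal))
  make_clip <- function(tag) {
    clip <- generate_behavior_clip(
      behavior_spec(tag, t_len = spec$t_len, jitter_sd = spec$jitter_sd))
    clip <- normalize_coordinates(clip, clip$frame_size[1L],
                                  clip$frame_size[2L])
    if (isTRUE(spec$canonicalize)) clip <- canonicalize_pose(clip)
    clip
  }
  train_clips <- list(); train_labels <- integer(0)
  test_clips <- list(); test_labels <- integer(0)
  for (ci in seq_along(spec$behaviors)) {
    n_train <- as.integer(round(spec$split_ratio * spec$n_per_class))
    for (i in seq_len(spec$n_per_class)) {
      clip <- make_clip(spec$behaviors[ci])
      if (i <= n_train) {
        train_clips[[length(train_clips) + 1L]] <- clip
        train_labels <- c(train_labels, ci)
      } else {
        test_clips[[length(test_clips) + 1L]] <- clip
        test_labels <- c(test_labels, ci)
      }
    }
  }
  truth <- rep(FALSE, length(test_clips))
  if (n_anom > 0L) {
    fams <- rep_len(ANOMALY_BEHAVIORS, n_anom)
    for (i in seq_len(n_anom)) {
      test_clips[[length(test_clips) + 1L]] <- make_clip(fams[i])
      test_labels <- c(test_labels, NA_integer_)
      truth <- c(truth, TRUE)
    }
  }
  list(
    train = clip_dataset(train_clips, labels = train_labels,
                         label_names = spec$behaviors,
                         split_tag = "train"),
    test = clip_dataset(test_clips, labels = test_labels,
                        label_names = spec$behaviors,
                        split_tag = "test"),
    truth = truth)
}

# centroid (mean over joints) trajectory of a clip, (T x 2), x/y channels
clip_centroid <- function(clip) {
  d <- dim(clip$data)
  cx <- apply(clip$data[1L, 1L, , , 1L, drop = FALSE], 3L, mean)
  cy <- apply(clip$data[1L, 2L, , , 1L, drop = FALSE], 3L, mean)
  cbind(x = cx, y = cy)
}
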