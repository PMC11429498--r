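# DLC CSV dialect, coordinate normalization, segmentation, archives.

make_dlc_csv <- function(path, joints, frames) {
  # frames: list of per-frame named lists joint -> c(x, y, lik)
  h1 <- paste(c("scorer", rep("test", 3 * length(joints))), collapse = ",")
  h2 <- paste(c("bodyparts", rep(joints, each = 3)), collapse = ",")
  h3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(joints))),
              collapse = ",")
  rows <- vapply(seq_along(frames), function(t) {
    vals <- unlist(lapply(joints, function(j) frames[[t]][[j]]))
    paste(c(t - 1, vals), collapse = ",")
  }, character(1))
  writeLines(c(h1, h2, h3, rows), path)
  path
}

test_that("DLC CSV values land in the right tensor cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  make_dlc_csv(path, c("nose", "tail_tip"),
               list(list(nose = c(1, 2, 0.9), tail_tip = c(5, 6, 0.7)),
                    list(nose = c(3, 4, 0.8), tail_tip = c(7, 8, 0.6))))
  s <- read_dlc_csv(path, c("nose", "tail_tip"))
  expect_equal(dim(s$data), c(1, 3, 2, 2, 1))
  expect_equal(s$data[1, 1, , 1, 1], c(1, 3))   # nose x
  expect_equal(s$data[1, 3, , 1, 1], c(0.9, 0.8))  # nose conf
  expect_equal(s$data[1, 2, , 2, 1], c(6, 8))   # tail y

  # joint order follows the request, not the file
  s2 <- read_dlc_csv(path, c("tail_tip", "nose"))
  expect_equal(s2$data[1, 1, , 1, 1], c(5, 7))
})

test_that("DLC CSV errors name the joint / row", {
  path <- withr::local_tempfile(fileext = ".csv")
  make_dlc_csv(path, "nose", list(list(nose = c(1, 2, 0.9))))
  expect_error(read_dlc_csv(path, c("nose", "ear")), "ear")
  writeLines(c("scorer,a,a,a", "bodyparts,nose,nose,nose",
               "coords,x,y,likelihood", "0,1.0,oops,0.5"), path)
  expect_error(read_dlc_csv(path, "nose"), "row 1")
  expect_error(read_dlc_csv(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("DLC write -> read is the identity on values", {
  set.seed(3)
  clip <- generate_behavior_clip(behavior_spec("movement", t_len = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dlc_csv(clip, path)
  back <- read_dlc_csv(path, clip$keypoint_names)
  expect_equal(back$data, clip$data, tolerance = 1e-12)
})

test_that("coordinate normalization centers and shares one scale", {
  mk <- function(x, y) {
    d <- array(0, dim = c(1, 3, 1, 1, 1))
    d[1, 1, 1, 1, 1] <- x; d[1, 2, 1, 1, 1] <- y
    skeleton_sequence(d, "nose")
  }
  ctr <- normalize_coordinates(mk(320, 240), 640, 480)
  expect_equal(ctr$data[1, 1:2, 1, 1, 1], c(0, 0))

  edge <- normalize_coordinates(mk(640, 240), 640, 480)
  expect_equal(edge$data[1, 1, 1, 1, 1], 1.0)

  # renormalizing with frame dims (2,2) composes affinely: under the
  # image convention the (2,2) frame midpoint is (1,1) and the shared
  # scale is 1, so the second pass is exactly (x - 1, y - 1)
  once <- normalize_coordinates(mk(123, 210), 640, 480)
  twice <- normalize_coordinates(once, 2, 2)
  expect_equal(twice$data[1, 1:2, 1, 1, 1],
               once$data[1, 1:2, 1, 1, 1] - 1)

  # invariant under joint rescaling of coordinates and frame
  a <- normalize_coordinates(mk(100, 50), 640, 480)
  b <- normalize_coordinates(mk(250, 125), 1600, 1200)
  expect_equal(a$data[1, 1:2, 1, 1, 1], b$data[1, 1:2, 1, 1, 1])

  expect_error(normalize_coordinates(mk(1, 1), 0, 480), "positive")
})

test_that("segmentation drops the remainder and keeps time order", {
  set.seed(4)
  long <- generate_behavior_clip(behavior_spec("movement", t_len = 120))
  ds <- segment_clips(long, 50)
  expect_length(ds$clips, 2)
  expect_equal(ds$clips[[1]]$data[1, , , , 1], long$data[1, , 1:50, , 1])
  expect_equal(ds$clips[[2]]$data[1, , , , 1], long$data[1, , 51:100, , 1])

  expect_length(segment_clips(generate_behavior_clip(
    behavior_spec("standing", t_len = 50)), 50)$clips, 1)
  expect_length(segment_clips(generate_behavior_clip(
    behavior_spec("standing", t_len = 49)), 50)$clips, 0)

  # count == floor(T / clip_len) across lengths
  for (t_len in c(2, 7, 49, 50, 51, 103)) {
    clip <- generate_behavior_clip(behavior_spec("turning", t_len = t_len))
    expect_length(segment_clips(clip, 25)$clips, t_len %/% 25)
  }
})

test_that("a written CSV re-read and segmented yields floor(T/50) clips", {
  set.seed(9)
  clip <- generate_behavior_clip(behavior_spec("movement", t_len = 100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dlc_csv(clip, path)
  expect_length(segment_clips(read_dlc_csv(path), 50)$clips,
                100 %/% 50)
})

test_that("dataset archive round trip is lossless and byte-stable", {
  empty <- clip_dataset(list())
  p0 <- withr::local_tempfile(fileext = ".rds")
  write_dataset(empty, p0)
  expect_length(read_dataset(p0)$clips, 0)

  set.seed(6)
  clips <- lapply(c("movement", "standing", "turning"), function(b)
    generate_behavior_clip(behavior_spec(b, t_len = 30)))
  ds <- clip_dataset(clips, labels = c(1, 2, 3),
                     label_names = c("movement", "standing", "turning"),
                     split_tag = "train")
  p1 <- withr::local_tempfile(fileext = ".rds")
  write_dataset(ds, p1)
  back <- read_dataset(p1)
  expect_equal(length(back$clips), 3)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$label_names, ds$label_names)
  for (i in 1:3) expect_equal(back$clips[[i]]$data, ds$clips[[i]]$data)

  # byte-stability: two writes of the same dataset are identical files
  p2 <- withr::local_tempfile(fileext = ".rds")
  write_dataset(ds, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  # corrupt archive
  writeLines("not an archive", p2)
  expect_error(read_dataset(p2), "archive")
})

test_that("clip_dataset validates shapes and labels", {
  set.seed(8)
  a <- generate_behavior_clip(behavior_spec("movement", t_len = 10))
  b <- generate_behavior_clip(behavior_spec("movement", t_len = 12))
  expect_error(clip_dataset(list(a, b)), "share")
  expect_error(clip_dataset(list(a), labels = c(1, 2)), "one entry")
  expect_error(clip_dataset(list(a), labels = 3L, label_names = "x"),
               "outside")
})

test_that("pose canonicalization removes position and heading", {
  set.seed(10)
  clip <- generate_behavior_clip(behavior_spec("movement", t_len = 15,
                                               jitter_sd = 0))
  canon <- canonicalize_pose(clip)
  kp <- clip$keypoint_names
  ax <- match(c("nose", "head", "neck", "spine_mid", "tail_base",
                "tail_tip"), kp)
  # first-frame body center at the origin, axis along +x (nose forward)
  expect_equal(mean(canon$data[1, 1, 1, ax, 1]), 0, tolerance = 1e-9)
  expect_equal(mean(canon$data[1, 2, 1, ax, 1]), 0, tolerance = 1e-9)
  ni <- match("nose", kp); ti <- match("tail_tip", kp)
  expect_equal(canon$data[1, 2, 1, ni, 1], 0, tolerance = 1e-6)
  expect_gt(canon$data[1, 1, 1, ni, 1], canon$data[1, 1, 1, ti, 1])

  # invariance: an arbitrary rigid motion of the input cancels out
  th <- 1.1; dx <- 37; dy <- -12
  rot <- clip
  x <- clip$data[1, 1, , , 1]; y <- clip$data[1, 2, , , 1]
  rot$data[1, 1, , , 1] <- cos(th) * x - sin(th) * y + dx
  rot$data[1, 2, , , 1] <- sin(th) * x + cos(th) * y + dy
  expect_equal(canonicalize_pose(rot)$data, canon$data, tolerance = 1e-8)
})
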