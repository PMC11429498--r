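# PCA reduction, DBSCAN clustering, anomaly flags, average precision.

test_that("PCA reduction matches an explicit eigendecomposition", {
  set.seed(51)
  x <- matrix(rnorm(50 * 16), 50, 16)
  fit <- pca_fit_reduce(x, 5)

  cov_m <- stats::cov(x)
  ev <- eigen(cov_m, symmetric = TRUE)
  for (j in 1:5) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(fit$rotation[, j], v, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_equal(fit$explained_variance_ratio,
               (ev$values / sum(ev$values))[1:5], tolerance = 1e-8)
  expect_true(all(diff(fit$explained_variance_ratio) <= 1e-12))

  # full-dimensional fit reconstructs exactly, ratios sum to 1
  full <- pca_fit_reduce(x, 16)
  recon <- full$scores %*% t(full$rotation) +
    matrix(full$center, 50, 16, byrow = TRUE)
  expect_equal(recon, x, tolerance = 1e-8)
  expect_equal(sum(full$explained_variance_ratio), 1)

  # collinear 2-D data: one component carries all variance
  line <- cbind(1:20, 2 * (1:20) + 3)
  expect_equal(pca_fit_reduce(line, 2)$explained_variance_ratio[1], 1)

  expect_error(pca_fit_reduce(x, 60), "exceeds")
  expect_error(pca_fit_reduce(x[1, , drop = FALSE], 1), "2 samples")

  # transform of the training data reproduces the scores
  expect_equal(pca_transform(fit, x), fit$scores)
})

test_that("DBSCAN follows the density-reachability contract", {
  expect_equal(dbscan_cluster(matrix(0, 1, 2), eps = 1, min_samples = 2),
               -1L)

  set.seed(52)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.1), rnorm(n, cy, 0.1))
  pts <- rbind(blob(0, 0, 20), blob(10, 0, 20), c(50, 50))
  lab <- dbscan_cluster(pts, eps = 0.5, min_samples = 5)
  expect_equal(length(setdiff(unique(lab), -1L)), 2)
  expect_equal(lab[41], -1L)
  expect_equal(length(unique(lab[1:20])), 1)
  expect_equal(length(unique(lab[21:40])), 1)

  # shuffling input leaves the partition unchanged (ids may permute)
  perm <- sample(nrow(pts))
  lab_p <- dbscan_cluster(pts[perm, ], eps = 0.5, min_samples = 5)
  back <- integer(nrow(pts)); back[perm] <- lab_p
  expect_equal(partition_sets(back), partition_sets(lab))

  # oracle equivalence on random instances
  for (trial in 1:10) {
    n <- sample(20:80, 1)
    p <- matrix(rnorm(n * 2, sd = sample(c(0.5, 2), 1)), n, 2)
    eps <- runif(1, 0.3, 1.5)
    ms <- sample(2:6, 1)
    expect_equal(partition_sets(dbscan_cluster(p, eps, ms)),
                 partition_sets(oracle_dbscan_partition(p, eps, ms)))
  }

  # growing eps never creates more noise points
  for (trial in 1:5) {
    p <- matrix(rnorm(60 * 2), 60, 2)
    noise_counts <- vapply(c(0.3, 0.6, 1.0, 1.5), function(e)
      sum(dbscan_cluster(p, e, 4) == -1L), numeric(1))
    expect_true(all(diff(noise_counts) <= 0))
  }
})

test_that("detect_abnormal flags exactly the planted outliers", {
  set.seed(53)
  # identical embeddings collapse into one cluster, nothing abnormal
  same <- matrix(1, 10, 4)
  rep0 <- detect_abnormal(same, pca_dims = 2, min_samples = 5)
  expect_equal(attr(rep0, "params")$num_clusters, 1)
  expect_false(any(rep0$is_abnormal))

  # four tight clusters + five far points
  centers <- rbind(c(0, 0), c(20, 0), c(0, 20), c(20, 20))
  emb <- do.call(rbind, lapply(1:4, function(i)
    cbind(rnorm(15, centers[i, 1], 0.3), rnorm(15, centers[i, 2], 0.3),
          rnorm(15, 0, 0.3), rnorm(15, 0, 0.3))))
  outliers <- cbind(runif(5, 60, 90), runif(5, 60, 90),
                    rnorm(5), rnorm(5))
  emb <- rbind(emb, outliers)
  report <- detect_abnormal(emb, pca_dims = 4, min_samples = 5)
  expect_equal(which(report$is_abnormal), 61:65)
  expect_equal(attr(report, "params")$num_clusters, 4)
  expect_identical(report$is_abnormal, report$cluster_id == -1L)
  expect_equal(sum(report$is_abnormal) + sum(!report$is_abnormal),
               nrow(emb))
  expect_true(all(report$anomaly_score >= 0))

  expect_error(detect_abnormal(emb[1:3, ], min_samples = 5), "at least")
})

test_that("average precision matches threshold enumeration", {
  # worked example: step-wise PR integral
  wk <- average_precision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(wk$ap, (1 + 2 / 3) / 2, tolerance = 1e-12)

  expect_equal(average_precision(c(5, 4, 1, 2), c(1, 1, 0, 0))$ap, 1.0)
  expect_equal(average_precision(rnorm(6), rep(1, 6))$ap, 1.0)
  expect_error(average_precision(1:4, rep(0, 4)), "positives")

  set.seed(54)
  for (trial in 1:100) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    truth <- rbinom(n, 1, 0.4)
    if (sum(truth) == 0) truth[1] <- 1
    expect_equal(average_precision(scores, truth)$ap,
                 oracle_ap(scores, truth), tolerance = 1e-12)
    # invariant under strictly monotone transforms of the scores
    expect_equal(average_precision(exp(3 * scores), truth)$ap,
                 average_precision(scores, truth)$ap, tolerance = 1e-12)
  }
})

test_that("report tidiers and JSON export are consistent", {
  set.seed(55)
  emb <- rbind(matrix(rnorm(40, sd = 0.2), 20, 2),
               matrix(rnorm(4, 30, 0.2), 2, 2))
  report <- detect_abnormal(emb, pca_dims = 2, min_samples = 4)
  gl <- glance(report)
  expect_equal(gl$n_clips, 22)
  expect_equal(gl$n_abnormal + gl$n_normal, 22)

  path <- withr::local_tempfile(fileext = ".json")
  write_anomaly_report(report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$clips$cluster_id, report$cluster_id)
  expect_equal(back$params$min_samples, 4)

  pr <- average_precision(report$anomaly_score, c(rep(0, 20), 1, 1))
  td <- tidy(pr)
  expect_true(all(td$precision >= 0 & td$precision <= 1))
  expect_true(all(diff(td$recall) >= 0))
  expect_equal(glance(pr)$ap, pr$ap)
})
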