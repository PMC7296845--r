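# Frame normalization, thresholds, the internalization statistic, clusters.

test_that("normalize_frame is the robust z-score with raw MAD", {
  nf <- normalize_frame(matrix(c(1, 2, 3, 4, 5), nrow = 1))
  expect_equal(as.vector(nf$values), c(-2, -1, 0, 1, 2))
  expect_identical(nf$source_median, 3)
  expect_identical(nf$source_mad, 1)
  expect_equal(median(nf$values), 0)

  expect_error(normalize_frame(matrix(7, 2, 2)), class = "mq_degenerate_frame")
  err <- tryCatch(normalize_frame(matrix(7, 2, 2)), condition = identity)
  expect_identical(err$frame_median, 7)
})

test_that("normalization is invariant under frame-global affine maps", {
  for (seed in 1:5) {
    f <- random_frame(seed = seed)
    a <- withr::with_seed(seed, runif(1, 0.1, 10))
    b <- withr::with_seed(seed + 100, runif(1, -50, 50))
    expect_equal(normalize_frame(a * f + b)$values, normalize_frame(f)$values,
                 tolerance = 1e-9)
  }
})

test_that("threshold estimators pool order statistics as documented", {
  # 1..100 pooled: type-7 99th percentile at position 1 + 0.99 * 99
  expect_equal(estimate_threshold_timelapse(list(matrix(1:100, 10)), n_baseline = 1),
               99.01)
  # constant pool
  expect_identical(estimate_threshold_timelapse(rep(list(matrix(5, 2, 2)), 4)), 5)
  # permuting pixels leaves the percentile unchanged
  f <- random_frame(seed = 8)
  fp <- matrix(sample(as.vector(f)), nrow(f))
  expect_equal(estimate_threshold_timelapse(list(f, f), n_baseline = 2),
               estimate_threshold_timelapse(list(fp, fp), n_baseline = 2))
  # pooling two half-pools equals one full pool
  expect_equal(estimate_threshold_static(list(matrix(1:50, 5), matrix(51:100, 5))),
               estimate_threshold_static(list(matrix(1:100, 10))))
  expect_identical(estimate_threshold_static(list(matrix(0, 3, 3))), 0)
  expect_error(estimate_threshold_static(list()), class = "mq_validation_error")
  expect_error(estimate_threshold_timelapse(list(matrix(1, 2, 2)), n_baseline = 4),
               class = "mq_validation_error")
})

test_that("sum_above_threshold applies a strict Iverson bracket", {
  expect_identical(sum_above_threshold(c(0, 1, 2, 3), 1), 5)
  expect_identical(sum_above_threshold(c(1, 1, 1), 2), 0)
  v <- random_frame(seed = 4)
  expect_equal(sum_above_threshold(v, min(v) - 1), sum(v))
  # boundary: pixels exactly at k contribute nothing
  expect_identical(sum_above_threshold(c(2, 2, 3), 2), 3)
})

test_that("S_int matches naive enumeration and is monotone in k", {
  for (seed in 1:25) {
    v <- withr::with_seed(seed, matrix(rnorm(12 * 12), 12))
    ks <- withr::with_seed(seed + 500, sort(runif(3, 0, 2)))
    s <- vapply(ks, function(k) sum_above_threshold(v, k), numeric(1))
    for (i in seq_along(ks)) expect_identical(s[i], naive_sint(v, ks[i]))
    expect_true(all(diff(s) <= 0))  # non-increasing in k
  }
})

test_that("quantify_timelapse: zero before onset, non-decreasing after, gain-proof", {
  sim <- monotone_cluster_stack(n_frames = 10, onset = 5)
  res <- quantify_timelapse(sim$stack)
  expect_true(all(res$per_frame_Sint[1:4] == 0))
  expect_true(all(diff(res$per_frame_Sint[5:10]) >= 0))

  gain <- seq(1, 2.5, length.out = 10)
  sim_g <- monotone_cluster_stack(n_frames = 10, onset = 5, gain = gain)
  res_g <- quantify_timelapse(sim_g$stack)
  expect_equal(res_g$per_frame_Sint, res$per_frame_Sint, tolerance = 1e-9)
  expect_equal(res_g$k, res$k, tolerance = 1e-9)
})

test_that("quantify_timelapse on pure noise keeps S_int near the baseline level", {
  spec <- stack_spec(32, 32, 12, background_noise_sd = 8, seed = 21)
  res <- quantify_timelapse(simulate_stack(spec)$stack)
  # ~1% of pixels exceed k in every frame; no trend, same scale throughout
  baseline <- median(res$per_frame_Sint[1:4])
  later <- median(res$per_frame_Sint[5:12])
  expect_lt(abs(later - baseline) / baseline, 0.5)
})

test_that("quantify_timelapse degenerate-frame policies behave as configured", {
  frames <- c(rep(list(matrix(5, 4, 4)), 4), list(random_frame(4, 4, seed = 2) ^ 2))
  stack <- frame_stack(frames)
  res <- quantify_timelapse(stack)
  expect_identical(res$degenerate_frames, 1:4)
  expect_error(quantify_timelapse(stack, degenerate = "error"),
               class = "mq_degenerate_frame")
  res_c <- quantify_timelapse(stack, degenerate = "centre-only")
  expect_identical(res_c$degenerate_frames, 1:4)
  expect_true(all(res_c$per_frame_Sint[1:4] == 0))
})

test_that("quantify_static matches direct enumeration when test equals control", {
  ctrl <- random_frame(20, 20, seed = 31)
  res <- quantify_static(list(ctrl), list(ctrl))
  nf <- normalize_frame(ctrl)$values
  k <- as.numeric(quantile(nf, 0.99, type = 7))
  expect_equal(res$per_frame_Sint, sum(nf[nf > k]))
  expect_equal(res$k, k)

  # a light-tailed (uniform) test image normalizes everywhere below the
  # Gaussian control's k: (x - median) / MAD <= 2 < k ~ 3.4
  low <- withr::with_seed(5, matrix(runif(400), 20))
  expect_gt(res$k, max(normalize_frame(low)$values))
  res2 <- quantify_static(list(low), list(ctrl))
  expect_identical(res2$per_frame_Sint, 0)
})

test_that("quantify_static exceedance mass is ~1% of pixels under the null", {
  ctrl <- lapply(1:6, function(s) random_frame(32, 32, seed = 100 + s))
  tests <- lapply(1:40, function(s) random_frame(32, 32, seed = 200 + s))
  res <- quantify_static(tests, ctrl)
  n_exceed <- vapply(tests, function(f) {
    nf <- normalize_frame(f)$values
    sum(nf > res$k)
  }, numeric(1))
  expect_gt(mean(n_exceed) / (32 * 32), 0.003)
  expect_lt(mean(n_exceed) / (32 * 32), 0.03)
})

test_that("count_clusters recovers planted disks and honours connectivity", {
  spec <- stack_spec(24, 24, 4, background_noise_sd = 0, seed = 2,
                     clusters = list(
                       cluster_spec(c(5, 5), 2, 1, 50),
                       cluster_spec(c(5, 18), 2, 1, 60),
                       cluster_spec(c(18, 12), 3, 1, 70)))
  sim <- simulate_stack(spec)
  frame1 <- mabquant:::normalize_with_fallback(sim$stack$frames[[1]])$values
  cc <- count_clusters(frame1, k = 0, min_area = 5)
  expect_identical(cc$n_clusters, 3L)
  expect_identical(cc$n_clusters, oracle_n_components(frame1 > 0, 8L))

  expect_identical(count_clusters(matrix(0, 5, 5), k = 0)$n_clusters, 0L)

  # two single pixels touching only diagonally
  m <- matrix(0, 4, 4); m[2, 2] <- 5; m[3, 3] <- 5
  expect_identical(count_clusters(m, 1, min_area = 1, connectivity = 8)$n_clusters, 1L)
  expect_identical(count_clusters(m, 1, min_area = 1, connectivity = 4)$n_clusters, 2L)

  # min_area filters small components and labels stay in raster order
  m2 <- matrix(0, 6, 10); m2[1:2, 1:3] <- 9; m2[5, 8] <- 9
  cc2 <- count_clusters(m2, 1, min_area = 2)
  expect_identical(cc2$n_clusters, 1L)
  expect_true(all(cc2$cluster_labels[m2 == 0] == 0))
})

test_that("component labelling agrees with the fixpoint oracle on random masks", {
  for (seed in 1:10) {
    mask <- withr::with_seed(seed, matrix(runif(100) < 0.35, 10))
    for (conn in c(4L, 8L)) {
      cc <- count_clusters(mask * 1.0, 0.5, min_area = 1, connectivity = conn)
      expect_identical(cc$n_clusters, oracle_n_components(mask, conn))
    }
  }
})

test_that("classify_rois flags planted positives and validates bounds", {
  img <- matrix(0, 10, 10)
  img[2:3, 2:3] <- 10   # positive ROI
  rois <- list(pos = img > 5,
               neg = matrix(rep(c(TRUE, FALSE), 50), 10, 10) & img < 5)
  rp <- classify_rois(img, rois, k = 1)
  expect_identical(rp$positive_flags, c(pos = TRUE, neg = FALSE))
  expect_identical(rp$fraction_positive, 0.5)
  expect_identical(rp$per_roi_Sint[["pos"]], 40)

  all_pos <- classify_rois(img, list(a = img > 5, b = img > 5), k = 1)
  expect_identical(all_pos$fraction_positive, 1)

  expect_error(classify_rois(img, list(bad = c(0L, 5L)), k = 1),
               class = "mq_roi_bounds_error")
  expect_error(classify_rois(img, list(bad = matrix(TRUE, 2, 2)), k = 1),
               class = "mq_roi_bounds_error")
})
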