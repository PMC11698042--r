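shift_map <- function(m, dr, dc) {
  out <- matrix(0L, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m) - abs(dr)); src_c <- seq_len(ncol(m) - abs(dc))
  out[src_r + max(dr, 0), src_c + max(dc, 0)] <-
    m[src_r - min(dr, 0), src_c - min(dc, 0)]
  out
}

test_that("instance matching counts TP/FP/FN at the IoU threshold", {
  m <- matrix(0L, 30, 30); m[3:12, 3:12] <- 1L; m[20:27, 20:27] <- 2L
  # identical maps
  r <- match_instances(m, m, 0.5)
  expect_equal(r$f1, 1); expect_equal(r$mean_matched_iou, 1)
  expect_equal(c(r$TP, r$FP, r$FN), c(2, 0, 0))
  # prediction missing one of two objects
  p <- m; p[p == 2L] <- 0L
  r2 <- match_instances(m, p, 0.5)
  expect_equal(r2$precision, 1)
  expect_equal(r2$recall, 0.5)
  expect_equal(r2$f1, 2 / 3)
  # 10x10 square shifted by 2 px: IoU = 80/120
  sq <- matrix(0L, 30, 30); sq[3:12, 3:12] <- 1L
  sh <- shift_map(sq, 0, 2)
  iou <- sum(sq & sh) / sum(sq | sh)
  expect_equal(iou, 80 / 120)
  expect_equal(match_instances(sq, sh, 0.5)$TP, 1)
  expect_equal(match_instances(sq, sh, 0.75)$TP, 0)
  expect_equal(match_instances(sq, sh, 0.75)$FN, 1)
  expect_error(match_instances(sq, matrix(0L, 5, 5)), "shape")
})

test_that("matching is invariant to label permutation of either input", {
  set.seed(13)
  lm <- random_label_scene(40, 40)
  m <- lm$labels
  pred <- shift_map(m, 1, 0)
  perm <- sample(max(m))
  mp <- m; mp[m > 0L] <- perm[m[m > 0L]]
  for (tau in c(0.3, 0.5, 0.75)) {
    a <- match_instances(m, pred, tau)
    b <- match_instances(mp, pred, tau)
    expect_equal(a[c("TP", "FP", "FN", "f1")], b[c("TP", "FP", "FN", "f1")])
  }
  pm <- partition_metrics(m, mp)
  expect_equal(pm$adapted_rand_error, 0, tolerance = 1e-12)
  expect_equal(pm$voi_split, 0, tolerance = 1e-12)
  expect_equal(pm$voi_merge, 0, tolerance = 1e-12)
})

test_that("F1 curves are non-increasing in tau", {
  m <- matrix(0L, 30, 30); m[3:12, 3:12] <- 1L; m[20:27, 20:27] <- 2L
  cv <- f1_curve(m, m)
  expect_true(all(cv$f1 == 1))
  cv0 <- f1_curve(m, matrix(0L, 30, 30))
  expect_true(all(cv0$f1 == 0))
  set.seed(17)
  for (rep in 1:5) {
    lm <- random_label_scene(48, 48)
    pred <- shift_map(lm$labels, sample(0:2, 1), sample(0:2, 1))
    cv2 <- f1_curve(lm$labels, pred)
    expect_true(all(diff(cv2$f1) <= 1e-12))
  }
})

test_that("percentage count error is symmetric and scaled to ground truth", {
  expect_equal(percent_count_error(100, 94), 6)
  expect_equal(percent_count_error(100, 106), 6)
  expect_equal(percent_count_error(50, 50), 0)
  expect_equal(percent_count_error(40, 50), 25)
  expect_error(percent_count_error(0, 5), "positive")
})

test_that("mask IoU handles the empty-mask conventions", {
  a <- matrix(FALSE, 10, 10); a[2:6, 2:6] <- TRUE
  expect_equal(mask_iou(a, a), 1)
  b <- matrix(FALSE, 10, 10); b[8:9, 8:9] <- TRUE
  expect_equal(mask_iou(a, b), 0)
  # half-overlapping equal rectangles: 50 / 150
  x <- matrix(FALSE, 20, 20); x[1:10, 1:10] <- TRUE
  y <- matrix(FALSE, 20, 20); y[6:15, 1:10] <- TRUE
  expect_equal(mask_iou(x, y), 1 / 3)
  e <- matrix(FALSE, 10, 10)
  expect_equal(mask_iou(e, e), 1)
  expect_equal(mask_iou(a, e), 0)
})

test_that("partition metrics recover the entropy of split/merge errors", {
  # gt = two equal halves, pred = one segment: voi_split = 1 bit
  gt <- matrix(rep(c(1L, 2L), each = 50), 10, 10)
  one <- matrix(1L, 10, 10)
  pm <- partition_metrics(gt, one)
  expect_equal(pm$voi_split, 1)
  expect_equal(pm$voi_merge, 0)
  # the mirror case: gt single, pred halves: voi_merge = 1 bit
  pm2 <- partition_metrics(one, gt)
  expect_equal(pm2$voi_split, 0)
  expect_equal(pm2$voi_merge, 1)
  # independent entropy oracle on an unequal split: H = -sum p log2 p
  gt3 <- matrix(c(rep(1L, 25), rep(2L, 75)), 10, 10)
  pm3 <- partition_metrics(gt3, one)
  expect_equal(pm3$voi_split, -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  # identity gives all zeros; background-only gt errors
  set.seed(23)
  lm <- random_label_scene(32, 32)
  pid <- partition_metrics(lm$labels, lm$labels)
  expect_equal(unlist(pid), c(adapted_rand_error = 0, voi_split = 0,
                              voi_merge = 0), tolerance = 1e-12)
  expect_error(partition_metrics(matrix(0L, 5, 5), matrix(1L, 5, 5)),
               "background")
  # adapted Rand error grows with a merge: hand-computed contingency
  pmm <- partition_metrics(gt, one)
  # precision = sum nij^2 / sum bj^2 = (50^2+50^2)/100^2 = 0.5; recall = 1
  expect_equal(pmm$adapted_rand_error, 1 - 2 * 0.5 * 1 / 1.5)
})

test_that("F1 equals the harmonic mean of precision and recall", {
  set.seed(29)
  for (rep in 1:5) {
    lm <- random_label_scene(40, 40)
    pred <- shift_map(lm$labels, 1, 1)
    r <- match_instances(lm$labels, pred, 0.5)
    if (r$precision + r$recall > 0) {
      expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
    }
  }
})
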