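chain_map <- function(gaps_px, ps = 1) {
  # 1-px-wide cells in a row with prescribed empty columns between them
  n <- length(gaps_px) + 1
  W <- 10 + n * 3 + sum(gaps_px) + 10
  m <- matrix(0L, 9, W)
  col <- 5
  for (k in seq_len(n)) {
    m[5, col] <- k
    if (k <= length(gaps_px)) col <- col + 1 + gaps_px[k]
  }
  label_map(m, ps)
}

test_that("edge gaps follow the minus-one-pixel convention", {
  cfg <- spatial_config(6.5, 26)
  # two 1-px cells with centers 11 px apart -> gap 10 um at 1 um/px
  m <- matrix(0L, 5, 20); m[3, 4] <- 1L; m[3, 15] <- 2L
  g <- edge_distance_graph(label_map(m, 1), spatial_config(6.5, 30))
  expect_equal(g$gap_um, 10)
  # 4-adjacent labels touch: gap 0
  m2 <- matrix(0L, 5, 10); m2[2:4, 3:5] <- 1L; m2[2:4, 6:8] <- 2L
  g2 <- edge_distance_graph(label_map(m2, 1), cfg)
  expect_equal(g2$gap_um, 0)
  # fewer than two cells -> empty graph
  m3 <- matrix(0L, 5, 5); m3[2, 2] <- 1L
  expect_equal(nrow(edge_distance_graph(label_map(m3, 1), cfg)), 0)
})

test_that("the distance graph equals the all-pairs brute force exactly", {
  cfg <- spatial_config(6.5, 26)
  set.seed(21)
  for (rep in 1:6) {
    lm <- random_label_scene(sample(30:64, 1), sample(30:64, 1))
    g1 <- edge_distance_graph(lm, cfg)
    g2 <- bf_edge_graph(lm, cfg)
    expect_identical(g1$i, g2$i)
    expect_identical(g1$j, g2$j)
    expect_identical(g1$gap_um, g2$gap_um)
  }
})

test_that("neighbor counts follow the inclusive threshold", {
  cfg <- spatial_config(6.5, 26)
  g <- edge_distance_graph(chain_map(c(5, 5)), cfg)
  expect_equal(pn_counts(g, cfg), c(1, 2, 1))
  # isolated cell
  g0 <- edge_distance_graph(chain_map(c(20)), cfg)
  expect_equal(pn_counts(g0, cfg), c(0, 0))
  # a gap of exactly T counts (inclusive rule); chain gap 6 px -> 6.5 um
  # at 1 um/px needs gap_um == T: use ps so that gap lands exactly on T
  lmT <- chain_map(c(13), ps = 0.5) # 13 px gap -> 6.5 um
  gT <- edge_distance_graph(lmT, cfg)
  expect_equal(gT$gap_um, 6.5)
  expect_equal(pn_counts(gT, cfg), c(1, 1))
})

test_that("neighbor counts are invariant under translation and rotation", {
  cfg <- spatial_config(6.5, 26)
  sc <- cached_small_scene()
  m <- sc$gt_cells$labels
  k0 <- pn_counts(edge_distance_graph(sc$gt_cells, cfg), cfg)
  # translation by whole pixels
  tr <- matrix(0L, nrow(m) + 7, ncol(m) + 3)
  tr[8:(7 + nrow(m)), 4:(3 + ncol(m))] <- m
  k1 <- pn_counts(edge_distance_graph(label_map(tr, 0.568), cfg), cfg)
  expect_identical(k1, k0)
  # 90 degree rotation
  rot <- t(m[nrow(m):1, ])
  k2 <- pn_counts(edge_distance_graph(label_map(rot, 0.568), cfg), cfg)
  expect_identical(k2, k0)
})

test_that("histograms are complete over k and normalize to one", {
  h <- pn_histogram(c(1, 2, 1))
  expect_equal(h, c(`0` = 0, `1` = 2, `2` = 1))
  hn <- pn_histogram(c(1, 2, 1), normalize = TRUE)
  expect_equal(sum(hn), 1)
  expect_equal(unname(hn[2:3]), c(2 / 3, 1 / 3))
  expect_equal(pn_histogram(c(0, 0), normalize = TRUE), c(`0` = 1))
  expect_error(pn_histogram(integer(0)), "no counts")
  # machine-precision normalization on a larger draw
  set.seed(2)
  k <- rpois(500, 3)
  expect_equal(sum(pn_histogram(k, normalize = TRUE)), 1)
})

test_that("cross-type counts restrict neighbors and centers", {
  cfg <- spatial_config(6.5, 26)
  g <- edge_distance_graph(chain_map(c(4, 4)), cfg)
  # chain A-B-C, neighbor flag only on B
  k <- cross_type_pn(g, c(FALSE, TRUE, FALSE), config = cfg)
  expect_equal(k, c(1, 0, 1))
  # all-true flags reduce to pn_counts
  expect_equal(cross_type_pn(g, rep(TRUE, 3), config = cfg),
               pn_counts(g, cfg))
  # centers restricted: only B reported, others NA
  kc <- cross_type_pn(g, rep(TRUE, 3), c(FALSE, TRUE, FALSE), cfg)
  expect_equal(kc, c(NA, 2, NA))
  expect_error(cross_type_pn(g, rep(TRUE, 3), rep(FALSE, 3), cfg),
               "no center")
})

test_that("cross-type means on independent flags match the thinning expectation", {
  # neighbors flagged independently with probability p: the expected
  # cross-type count is p times the expected plain count
  cfg <- spatial_config(6.5, 26)
  sc <- cached_small_scene()
  g <- edge_distance_graph(sc$gt_cells, cfg)
  k <- pn_counts(g, cfg)
  set.seed(31)
  p <- 0.5
  diffs <- replicate(300, {
    fl <- runif(length(k)) < p
    mean(cross_type_pn(g, fl, config = cfg))
  })
  expect_lt(abs(mean(diffs) - p * mean(k)), 3 * sd(diffs) / sqrt(300))
})

test_that("neighbor count maps paint cells with k over a -1 background", {
  m <- matrix(0L, 6, 10); m[2:3, 2:3] <- 1L; m[5, 7:8] <- 2L
  lm <- label_map(m, 1)
  nm <- neighbor_count_map(lm, c(1, 3))
  expect_setequal(unique(as.vector(nm)), c(-1, 1, 3))
  expect_equal(nm[2, 2], 1)
  expect_equal(nm[5, 7], 3)
  # repaint is idempotent
  expect_identical(neighbor_count_map(lm, c(1, 3)), nm)
  # empty labels -> all -1
  expect_true(all(neighbor_count_map(label_map(matrix(0L, 4, 4)),
                                     integer(0)) == -1))
  expect_error(neighbor_count_map(lm, c(1)), "missing")
})

test_that("local thickness matches its defining examples", {
  # centered disc of radius 10 px -> max LT ~ 20 px at the center
  m <- matrix(FALSE, 41, 41)
  for (i in 1:41) for (j in 1:41)
    if ((i - 21)^2 + (j - 21)^2 <= 100) m[i, j] <- TRUE
  lt <- local_thickness(m)
  expect_lt(abs(max(lt) - 20), 1)
  expect_equal(lt[21, 21], max(lt)) # the center attains the maximum
  # 4 x 20 solid bar -> LT = 4 px across the interior
  m2 <- matrix(FALSE, 20, 40); m2[9:12, 5:35] <- TRUE
  lt2 <- local_thickness(m2)
  expect_true(all(lt2[9:12, 15:25] == 4))
  # 1-px-wide line -> LT = 1 px (single-pixel disc convention)
  m3 <- matrix(FALSE, 11, 30); m3[6, 5:25] <- TRUE
  expect_true(all(local_thickness(m3)[m3] == 1))
  # empty mask -> all zero; calibration scales values
  expect_true(all(local_thickness(matrix(FALSE, 5, 5)) == 0))
  expect_equal(max(local_thickness(m2, 0.5)), 2)
})

test_that("local thickness equals the brute-force disc search exactly", {
  set.seed(77)
  for (rep in 1:6) {
    H <- sample(20:48, 1); W <- sample(20:48, 1)
    x <- matrix(runif(H * W), H, W)
    mask <- enteroquant:::.gauss_blur(x, 2) > quantile(x, 0.6)
    expect_identical(local_thickness(mask), bf_local_thickness(mask))
  }
})

test_that("threshold estimation measures intra-ganglionic spacing", {
  sc <- cached_small_scene()
  est <- estimate_threshold(sc$gt_cells, sc$gt_ganglia)
  expect_gt(est$mean_um, 0)
  expect_equal(est$n_pixels,
               sum(sc$gt_ganglia$labels > 0 & sc$gt_cells$labels == 0))
  # suggestion is the mean rounded up to the next 0.5 um
  expect_gte(est$suggested_threshold_um, est$mean_um)
  expect_lt(est$suggested_threshold_um - est$mean_um, 0.5)
  expect_equal(est$suggested_threshold_um %% 0.5, 0)
  # a mean spacing of 6.32 um maps to the 6.5 um default
  expect_equal(ceiling(6.32 / 0.5) * 0.5, 6.5)
  # region fully occupied by cells -> error
  full <- label_map(matrix(1L, 8, 8), 1)
  gm <- ganglia_from_labels(label_map(matrix(1L, 8, 8), 1))
  expect_error(estimate_threshold(full, gm), "no intra-ganglionic")
})
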