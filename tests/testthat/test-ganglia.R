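two_cell_map <- function(gap_px, ps = 1) {
  m <- matrix(0L, 20, 40)
  m[8:12, 5:10] <- 1L
  m[8:12, (11 + gap_px):(16 + gap_px)] <- 2L
  label_map(m, ps)
}

test_that("expansion merges cells exactly when the gap is below twice the radius", {
  # gap 4 um, expand 3 um -> merged (4 < 6)
  expect_equal(n_objects(ganglia_by_expansion(two_cell_map(4), 3)), 1)
  # gap 8 um, expand 3 um -> separate (8 > 6)
  expect_equal(n_objects(ganglia_by_expansion(two_cell_map(8), 3)), 2)
  # single cell -> one ganglion at least as large as the cell
  m <- matrix(0L, 20, 20); m[6:10, 6:10] <- 1L
  g <- ganglia_by_expansion(label_map(m, 1), 2)
  expect_equal(n_objects(g), 1)
  expect_gte(sum(g$labels > 0), 25)
  # empty input -> empty mask
  expect_equal(n_objects(ganglia_by_expansion(label_map(matrix(0L, 5, 5)))), 0)
})

test_that("expansion with radius 0 returns the connected components of the union", {
  sc <- cached_small_scene()
  g0 <- ganglia_by_expansion(sc$gt_cells, 0)
  cc <- enteroquant:::cpp_label_cc(sc$gt_cells$labels > 0L, 8L)
  expect_equal(n_objects(g0), max(cc))
  expect_identical(g0$labels > 0L, sc$gt_cells$labels > 0L)
})

test_that("increasing the expansion radius never increases the ganglion count", {
  sc <- cached_small_scene()
  radii <- c(0, 1, 2, 4, 8, 16)
  counts <- vapply(radii, function(r)
    n_objects(ganglia_by_expansion(sc$gt_cells, r)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("probability maps are thresholded inclusively and size-filtered", {
  expect_equal(n_objects(ganglia_from_probability(matrix(0.9, 12, 12))), 1)
  expect_equal(n_objects(ganglia_from_probability(matrix(0.5, 12, 12))), 0)
  pm <- matrix(0.1, 20, 40)
  pm[5:15, 3:15] <- 0.85
  pm[5:15, 25:38] <- 0.85
  g <- ganglia_from_probability(pm, 0.8)
  expect_equal(n_objects(g), 2)
  expect_error(ganglia_from_probability(matrix(1.5, 4, 4)), "\\[0, 1\\]")
  # min-area filter removes specks
  pm2 <- matrix(0, 20, 20); pm2[3, 3] <- 1; pm2[10:16, 10:16] <- 1
  expect_equal(n_objects(ganglia_from_probability(pm2, 0.8,
                                                  min_area_um2 = 5)), 1)
})

test_that("cells are assigned to the maximally overlapping ganglion", {
  cl <- matrix(0L, 20, 30)
  cl[5:8, 3:6] <- 1L       # inside ganglion 2
  cl[12:16, 10:19] <- 2L   # split 60/40 between ganglia 1 and 3
  cl[2:4, 25:28] <- 3L     # outside all ganglia
  gg <- matrix(0L, 20, 30)
  gg[11:18, 14:22] <- 1L   # covers 40 % of cell 2... (cols 14:19 of 10:19)
  gg[3:10, 1:8] <- 2L
  gg[10:18, 8:13] <- 3L    # covers cols 10:13 of cell 2
  # make ganglion 1 the 60 % owner: cols 14:19 = 6 of 10; g3 cols 10:13 = 4
  gmask <- ganglia_from_labels(label_map(gg, 1))
  cells <- build_cell_table(label_map(cl, 1))
  cells <- assign_cells(cells, label_map(cl, 1), gmask)
  expect_equal(cells$ganglion_id, c(2L, 1L, NA))
  # conservation: assigned + unassigned = total
  expect_equal(sum(!is.na(cells$ganglion_id)) + sum(is.na(cells$ganglion_id)),
               nrow(cells))
})

test_that("ties in overlap go to the lowest ganglion id", {
  cl <- matrix(0L, 10, 10); cl[4:5, 4:7] <- 1L
  gg <- matrix(0L, 10, 10); gg[1:10, 4:5] <- 2L; gg[1:10, 6:7] <- 1L
  cells <- build_cell_table(label_map(cl, 1))
  cells <- assign_cells(cells, label_map(cl, 1),
                        ganglia_from_labels(label_map(gg, 1)))
  expect_equal(cells$ganglion_id, 1L)
})

test_that("ganglion statistics summarize counts, areas and density", {
  sc <- cached_small_scene()
  cells <- build_cell_table(sc$gt_cells)
  cells <- assign_cells(cells, sc$gt_cells, sc$gt_ganglia)
  st <- ganglia_stats(cells, sc$gt_ganglia)
  expect_equal(st$summary$n_ganglia, 2)
  expect_equal(sum(st$per_ganglion$n_cells),
               sum(!is.na(cells$ganglion_id)))
  expect_equal(st$summary$neurons_per_mm2,
               sum(!is.na(cells$ganglion_id)) /
                 (st$summary$total_area_um2 / 1e6))
  # hand-checked summaries: counts {3, 5} -> mean 4, median 4
  fake <- data.frame(id = 1:8, ganglion_id = c(rep(1L, 3), rep(2L, 5)))
  gm <- ganglia_from_labels(label_map(matrix(c(rep(1L, 50), rep(2L, 50)),
                                             10, 10), 1))
  st2 <- ganglia_stats(fake, gm)
  expect_equal(st2$summary$mean_cells, 4)
  expect_equal(st2$summary$median_cells, 4)
  # 67 cells over 0.0268 mm^2 of ganglionic area -> 2500 cells per mm^2
  gmd <- ganglia_from_labels(label_map(matrix(1L, 67, 100), 2)) # 26800 um^2
  std <- ganglia_stats(data.frame(id = 1:67, ganglion_id = rep(1L, 67)), gmd)
  expect_equal(std$summary$total_area_um2, 26800)
  expect_equal(std$summary$neurons_per_mm2, 2500)
  gm3 <- ganglia_from_labels(label_map(matrix(rep(1:3, each = 40), 10, 12), 1))
  fake3 <- data.frame(id = 1:24,
                      ganglion_id = rep(c(1L, 2L, 3L), c(2L, 2L, 20L)))
  st3 <- ganglia_stats(fake3, gm3)
  expect_equal(st3$summary$mean_cells, 8)
  expect_equal(st3$summary$median_cells, 2) # robust to one giant ganglion
  # no ganglia -> empty stats
  st0 <- ganglia_stats(fake, ganglia_from_labels(label_map(matrix(0L, 5, 5))))
  expect_equal(st0$summary$n_ganglia, 0)
  expect_equal(nrow(st0$per_ganglion), 0)
})
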