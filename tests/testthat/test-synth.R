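test_that("generation is deterministic and respects programmed structure", {
  a <- generate_scene(small_spec(seed = 4))
  b <- generate_scene(small_spec(seed = 4))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$gt_cells$labels, b$gt_cells$labels)
  expect_identical(a$gt_flags, b$gt_flags)
  # two ganglia with exactly five cells each
  sp <- scene_spec(shape = c(512, 512), n_ganglia = 2,
                   cells_per_ganglion = list(mean = 5, sd = 0, min = 5),
                   seed = 9)
  sc <- generate_scene(sp)
  expect_equal(n_objects(sc$gt_cells), 10)
  expect_equal(n_objects(sc$gt_ganglia), 2)
  # each ganglion is a single 8-connected component
  for (gi in 1:2) {
    cc <- enteroquant:::cpp_label_cc(sc$gt_ganglia$labels == gi, 8L)
    expect_equal(max(cc), 1)
  }
})

test_that("drawn gaps honor the truncation bounds and the programmed mean", {
  sc <- cached_small_scene(seed = 2)
  g <- sc$spec$gap_um
  drawn <- vapply(sc$cells, function(cl) cl$gap, numeric(1))
  drawn <- drawn[!is.na(drawn)]
  expect_true(all(drawn >= g$min & drawn <= g$max))
  mu_t <- enteroquant:::.truncnorm_mean(g$mean, g$sd, g$min, g$max)
  se <- sd(drawn) / sqrt(length(drawn))
  expect_lt(abs(mean(drawn) - mu_t), 3 * se + 0.5)
})

test_that("marker flags hit programmed proportions within the binomial CI", {
  sp <- scene_spec(shape = c(1024, 1024), n_ganglia = 3,
                   cells_per_ganglion = list(mean = 20, sd = 3, min = 15),
                   marker_proportions = c(m1 = 0.3), seed = 5)
  sc <- generate_scene(sp)
  n <- nrow(sc$gt_flags)
  expect_gt(n, 50)
  ci <- qnorm(0.995) * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(sc$gt_flags$m1) - 0.3), ci)
})

test_that("truth summaries report programmed versus realized quantities", {
  sc <- cached_small_scene()
  ts <- truth_summary(sc)
  expect_equal(ts$realized[ts$quantity == "n_cells"],
               n_objects(sc$gt_cells))
  # realized mean soma area within 10 % of the calibration target
  a <- ts$realized[ts$quantity == "mean_area_px2"]
  expect_lt(abs(a - 701.2) / 701.2, 0.10)
  # drawn gap mean within 2 SE + discretization of the programmed mean
  drawn <- vapply(sc$cells, function(cl) cl$gap, numeric(1))
  se <- sd(drawn, na.rm = TRUE) / sqrt(sum(!is.na(drawn)))
  expect_lt(abs(ts$realized[ts$quantity == "gap_mean_um"] -
                  ts$programmed[ts$quantity == "gap_mean_um"]),
            2 * se + 1)
})

test_that("stretching scales areas and preserves identities", {
  sc <- cached_small_scene(seed = 6)
  # identity stretch reproduces the scene bit for bit
  st1 <- stretch_scene(sc, 1, 1)
  expect_identical(st1$gt_cells$labels, sc$gt_cells$labels)
  expect_identical(st1$image$pixels, sc$image$pixels)
  # 1.25 x 1.25: total ground-truth cell area scales by 1.5625 +- 3 %
  st <- stretch_scene(sc, 1.25, 1.25)
  ratio <- sum(st$gt_cells$labels > 0) / sum(sc$gt_cells$labels > 0)
  expect_lt(abs(ratio - 1.5625) / 1.5625, 0.03)
  expect_equal(n_objects(st$gt_cells), n_objects(sc$gt_cells))
  expect_identical(st$gt_flags, sc$gt_flags)
  # ganglionic density scales by 1/(sx sy) +- 5 %
  dens <- function(s) {
    cells <- assign_cells(build_cell_table(s$gt_cells), s$gt_cells,
                          s$gt_ganglia)
    ganglia_stats(cells, s$gt_ganglia)$summary$neurons_per_mm2
  }
  expect_lt(abs(dens(st) / dens(sc) - 1 / 1.5625) / (1 / 1.5625), 0.05)
  expect_error(stretch_scene(sc, 0.8, 1), ">= 1")
})

test_that("ground truth flows through the pipeline without loss", {
  # pipeline closure: gt labels in -> zero count error, F1 = 1 at 0.5,
  # exact marker proportions
  sc <- cached_small_scene()
  lab <- sc$gt_cells
  expect_equal(percent_count_error(n_objects(sc$gt_cells), n_objects(lab)), 0)
  expect_equal(match_instances(sc$gt_cells, lab, 0.5)$f1, 1)
  cells <- build_cell_table(lab, sc$image)
  for (mk in names(sc$spec$marker_proportions)) {
    fl <- positive_by_overlap(cells, lab, gt_subtype_map(sc, mk))
    expect_equal(mean(fl), mean(sc$gt_flags[[mk]]))
  }
})
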