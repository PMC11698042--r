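test_that("calibrated TIFF roundtrip preserves values, channels and pixel size", {
  img <- calibrated_image(list(hu = matrix(runif(15 * 20), 15, 20),
                               nnos = matrix(runif(15 * 20), 15, 20)),
                          pixel_size_um = 0.568)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_calibrated_image(img, tf)
  back <- read_calibrated_image(tf)
  expect_equal(back$pixel_size_um, 0.568, tolerance = 1e-7)
  expect_equal(length(back$pixels), 2)
  # stored as 32-bit floats
  expect_lt(max(abs(back$pixels[[1]] - img$pixels[[1]])), 1e-6)
  # float32-representable data round-trips bit exactly
  q <- matrix(round(runif(100) * 1024) / 1024, 10, 10)
  img2 <- calibrated_image(q, 2)
  write_calibrated_image(img2, tf)
  expect_identical(read_calibrated_image(tf)$pixels[[1]], q)
})

test_that("pixel size parsing covers resolution units and the missing-tag default", {
  ps <- enteroquant:::.pixel_size_from_info
  # 2 pixels per micrometre, unitless -> 0.5 um/px
  expect_equal(ps(list(x.resolution = 2, resolution.unit = "none")), 0.5)
  expect_equal(ps(list(x.resolution = 1e4, resolution.unit = "cm")), 1.0)
  expect_equal(ps(list(x.resolution = 25400, resolution.unit = "inch")), 1.0)
  expect_true(is.na(ps(list())))
  # a TIFF written without resolution metadata reads as 1 um/px + warning
  tf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(12), 3, 4), tf)
  expect_warning(img <- read_calibrated_image(tf), "resolution")
  expect_equal(img$pixel_size_um, 1.0)
})

test_that("label map roundtrip is bit-exact and validation rejects bad input", {
  lm <- label_map(matrix(sample(c(0L, 1L, 2L), 64 * 64, TRUE), 64, 64), 0.5)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_label_map(lm, tf)
  back <- read_label_map(tf)
  expect_identical(back$labels, lm$labels)
  expect_equal(back$pixel_size_um, 0.5, tolerance = 1e-7)
  # all-zero map is valid with 0 objects
  z <- label_map(matrix(0L, 8, 8))
  write_label_map(z, tf)
  expect_equal(n_objects(read_label_map(tf)), 0)
  # non-integral values rejected
  expect_error(label_map(matrix(c(0, 1.5, 2, 0), 2, 2)), "non-integral")
})

test_that("compaction maps labels {0,5,9} to {0,1,2}", {
  m <- matrix(0L, 4, 4); m[1, 1] <- 5L; m[3, 3] <- 9L
  cm <- compact_labels(label_map(m))
  expect_setequal(unique(as.vector(cm$labels)), c(0L, 1L, 2L))
  expect_equal(n_objects(cm), 2)
  expect_equal(cm$labels[1, 1], 1L)
  expect_equal(cm$labels[3, 3], 2L)
})

test_that("ROI archives round-trip through the ImageJ binary dialect", {
  r1 <- polygon_roi(c(2, 10, 10, 2), c(3, 3, 8, 8), "sq")
  r2 <- polygon_roi(c(12.25, 18.5, 15), c(2, 2.75, 9), "tri")
  zf <- withr::local_tempfile(fileext = ".zip")
  write_roi_archive(list(r1, r2), zf)
  back <- read_roi_archive(zf)
  expect_length(back, 2)
  expect_equal(back[[1]]$name, "sq")
  # sub-pixel float coordinates survive to float32 precision
  expect_equal(back[[1]]$x, r1$x, tolerance = 1e-6)
  expect_equal(back[[2]]$y, r2$y, tolerance = 1e-6)
  # single .roi file
  rf <- withr::local_tempfile(fileext = ".roi")
  write_roi_archive(list(r1), rf)
  expect_equal(read_roi_archive(rf)[[1]]$x, r1$x, tolerance = 1e-6)
})

test_that("oval ROIs become polygons with the analytic ellipse area", {
  # hand-built oval ROI: type 2, bounding box 10 x 10 at (0, 0)
  con <- rawConnection(raw(0), "wb")
  writeBin(charToRaw("Iout"), con)
  writeBin(as.integer(c(218L)), con, size = 2, endian = "big")
  writeBin(as.raw(c(2L, 0L)), con)                     # type oval
  for (v in c(0L, 0L, 10L, 10L, 0L))                    # top,left,bottom,right,n
    writeBin(v, con, size = 2, endian = "big")
  writeBin(raw(46), con)
  blob <- rawConnectionValue(con); close(con)
  rf <- withr::local_tempfile(fileext = ".roi")
  writeBin(blob, rf)
  rois <- read_roi_archive(rf)
  expect_length(rois, 1)
  expect_equal(roi_area(rois[[1]]), pi * 25, tolerance = 0.02)
})

test_that("corrupted headers fail loudly and unsupported types are skipped", {
  rf <- withr::local_tempfile(fileext = ".roi")
  writeBin(c(charToRaw("Xout"), raw(80)), rf)
  expect_error(read_roi_archive(rf), "Iout")
  # line ROI (type 3) is skipped with a warning, not an error
  con <- rawConnection(raw(0), "wb")
  writeBin(charToRaw("Iout"), con)
  writeBin(218L, con, size = 2, endian = "big")
  writeBin(as.raw(c(3L, 0L)), con)
  writeBin(raw(56), con)
  blob <- rawConnectionValue(con); close(con)
  writeBin(blob, rf)
  expect_warning(out <- read_roi_archive(rf), "unsupported")
  expect_length(out, 0)
})

test_that("rasterization paints pixel centers with later-wins overlap", {
  a <- polygon_roi(c(1.5, 5.5, 5.5, 1.5), c(1.5, 1.5, 4.5, 4.5))
  b <- polygon_roi(c(7.5, 11.5, 11.5, 7.5), c(1.5, 1.5, 4.5, 4.5))
  lab <- rasterize_rois(list(a, b), c(10, 14))
  expect_equal(sum(lab$labels == 1L), 4 * 3)
  expect_equal(sum(lab$labels == 2L), 4 * 3)
  # overlapping squares: the later ROI wins on shared pixels
  c2 <- polygon_roi(c(3.5, 8.5, 8.5, 3.5), c(1.5, 1.5, 4.5, 4.5))
  lab2 <- rasterize_rois(list(a, c2), c(10, 14))
  expect_equal(sum(lab2$labels == 2L), 5 * 3)
  expect_equal(sum(lab2$labels == 1L), 2 * 3)
  # empty ROI list -> all-zero map
  expect_equal(n_objects(rasterize_rois(list(), c(5, 5))), 0)
})

test_that("rasterized area agrees with point-in-polygon and shoelace bounds", {
  skip_if_not_installed("sp")
  set.seed(11)
  for (rep in 1:10) {
    m <- sample(5:12, 1)
    th <- sort(runif(m, 0, 2 * pi))
    rad <- runif(m, 4, 11)
    x <- 20 + rad * cos(th) + runif(1)
    y <- 20 + rad * sin(th) + runif(1)
    roi <- polygon_roi(x, y)
    lab <- rasterize_rois(list(roi), c(40, 40))
    # oracle: sp point-in-polygon over all pixel centers (boundary-free
    # vertices, so the even-odd fill must agree exactly)
    gx <- rep(0:39, each = 40); gy <- rep(0:39, 40)
    inside <- sp::point.in.polygon(gx, gy, roi$x, roi$y) > 0
    expect_equal(sum(lab$labels > 0), sum(inside))
    # discretization bound: |raster - shoelace| < boundary length
    per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
    expect_lt(abs(sum(lab$labels > 0) - roi_area(roi)), per)
  }
})

test_that("cell tables round-trip through CSV", {
  sc <- cached_small_scene()
  tab <- build_cell_table(sc$gt_cells, sc$image)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(tab, tf)
  back <- read_cell_table(tf)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$area_um2, tab$area_um2, tolerance = 1e-6)
  expect_equal(back$mean_hu, tab$mean_hu, tolerance = 1e-6)
  # empty table -> header-only file
  empty <- build_cell_table(label_map(matrix(0L, 4, 4)))
  write_cell_table(empty, tf)
  expect_equal(nrow(read_cell_table(tf)), 0)
  expect_gt(length(names(read_cell_table(tf))), 3)
})
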