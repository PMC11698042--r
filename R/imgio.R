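# Image, label-map and ROI input/output.
#
# Coordinate convention used throughout the package: rasters are indexed
# (row, col) with the origin at the top-left corner, 0-based; polygon
# vertices are (x = col, y = row) pixel-center coordinates.  Areas are
# reported in um^2 = pixel count x pixel_size_um^2.

#' Calibrated multi-channel image
#'
#' Container for a 2D intensity raster with a physical, isotropic pixel
#' size. Channels are stored as a list of numeric matrices sharing one
#' shape.
#'
#' @param pixels a numeric matrix (single channel) or a list of numeric
#'   matrices (one per channel), indexed (row, col).
#' @param pixel_size_um physical size of one pixel in micrometres
#'   (isotropic; anisotropic images are rejected upstream).
#' @param channel_names character vector naming the channels; defaults to
#'   `"ch0"`, `"ch1"`, ...
#' @return an object of class `calibrated_image` with fields `pixels`
#'   (list of matrices), `pixel_size_um` and `channel_names`.
#' @export
calibrated_image <- function(pixels, pixel_size_um = 1.0,
                             channel_names = NULL) {
  if (is.matrix(pixels)) pixels <- list(pixels)
  if (!is.list(pixels) || !all(vapply(pixels, is.matrix, logical(1))))
    .eq_stop("'pixels' must be a matrix or a list of matrices")
  dims <- vapply(pixels, dim, integer(2))
  if (length(pixels) > 1 && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    .eq_stop("all channels must share one shape")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    .eq_stop("'pixel_size_um' must be a single positive number")
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(names(pixels)) && all(names(pixels) != ""))
      names(pixels)
    else paste0("ch", seq_along(pixels) - 1)
  }
  if (length(channel_names) != length(pixels))
    .eq_stop("'channel_names' must have one entry per channel")
  pixels <- lapply(pixels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  names(pixels) <- channel_names
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel_names = channel_names),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels[[1]])
  cat(sprintf("calibrated_image: %d x %d px, %d channel(s) [%s], %.4g um/px\n",
              d[1], d[2], length(x$pixels),
              paste(x$channel_names, collapse = ", "), x$pixel_size_um))
  invisible(x)
}

#' Instance label map
#'
#' A 2D non-negative integer raster in which 0 is background and each
#' positive value is one object instance.
#'
#' @param labels integer matrix of instance labels, 0 = background.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return an object of class `label_map`.
#' @export
label_map <- function(labels, pixel_size_um = 1.0) {
  if (!is.matrix(labels)) .eq_stop("'labels' must be a matrix")
  if (is.double(labels)) {
    if (any(is.finite(labels) & labels != round(labels)))
      .eq_stop("label raster contains non-integral values")
    storage.mode(labels) <- "integer"
  }
  if (any(labels < 0, na.rm = TRUE)) .eq_stop("labels must be >= 0")
  if (pixel_size_um <= 0) .eq_stop("'pixel_size_um' must be positive")
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d x %d px, %d object(s), %.4g um/px\n",
              nrow(x$labels), ncol(x$labels), n_objects(x), x$pixel_size_um))
  invisible(x)
}

#' Number of distinct objects in a label map
#' @param labels a `label_map` or integer matrix.
#' @return integer count of distinct positive labels.
#' @export
n_objects <- function(labels) {
  m <- if (inherits(labels, "label_map")) labels$labels else labels
  length(setdiff(unique(as.vector(m)), 0L))
}

#' Compact labels to consecutive 1..n
#'
#' Remaps the positive labels of a label map to consecutive integers
#' 1..n, preserving their relative order.
#'
#' @param labels a `label_map` or integer matrix.
#' @return object of the same kind with compacted labels.
#' @export
compact_labels <- function(labels) {
  lm <- inherits(labels, "label_map")
  m <- if (lm) labels$labels else labels
  u <- sort(setdiff(unique(as.vector(m)), 0L))
  if (length(u) > 0 && !identical(u, seq_along(u))) {
    lut <- integer(max(u) + 1L)
    lut[u + 1L] <- seq_along(u)
    m2 <- matrix(lut[m + 1L], nrow(m), ncol(m))
  } else {
    m2 <- m
  }
  if (lm) label_map(m2, labels$pixel_size_um) else m2
}

# ---- TIFF ------------------------------------------------------------------

# pixel size (um) from readTIFF info attributes; NA when absent
.pixel_size_from_info <- function(a) {
  xres <- a[["x.resolution"]]
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NA_real_)
  unit <- a[["resolution.unit"]]
  if (is.null(unit)) unit <- "none"
  switch(unit,
         cm = 1e4 / xres,
         inch = 25400 / xres,
         # unitless resolution is interpreted as pixels per micrometre
         1 / xres)
}

#' Read a calibrated TIFF image
#'
#' Reads a single- or multi-channel 2D TIFF. The pixel size is parsed
#' from the TIFF resolution tags (resolution unit `cm` or `inch`; a
#' unitless resolution is interpreted as pixels per micrometre). When no
#' resolution metadata is present the pixel size defaults to 1 um/px and
#' a warning is issued.
#'
#' @param path path to a TIFF file. Multi-page files are read as one
#'   channel per page.
#' @param pixel_size_um optional override of the parsed pixel size.
#' @return a [calibrated_image].
#' @export
read_calibrated_image <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) .eq_stop("file not found: ", path)
  pages <- tiff::readTIFF(path, info = TRUE, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  chans <- list()
  for (p in pages) {
    d <- dim(p)
    if (length(d) == 2) {
      chans[[length(chans) + 1L]] <- unclass(p)
    } else if (length(d) == 3) {
      for (k in seq_len(d[3])) chans[[length(chans) + 1L]] <- p[, , k]
    } else {
      .eq_stop("unsupported TIFF with ", length(d), " axes: ", path)
    }
  }
  chans <- lapply(chans, function(m) {
    attributes(m) <- list(dim = dim(m))
    m
  })
  ps <- .pixel_size_from_info(attributes(pages[[1]]))
  if (is.na(ps)) {
    ps <- 1.0
    .eq_warn("no resolution metadata in ", path,
             "; assuming pixel size 1 um/px")
  }
  if (!is.null(pixel_size_um)) ps <- pixel_size_um
  calibrated_image(chans, ps)
}

# resolution (px/cm) as a uint32 rational
.res_rational <- function(pixel_size_um) {
  ppcm <- 1e4 / pixel_size_um
  den <- 10000
  while (ppcm * den > 2^31 - 1 && den > 1) den <- den / 10
  c(num = round(ppcm * den), den = den)
}

# Minimal little-endian TIFF writer (uncompressed, one strip per page,
# grayscale). The bundled 'tiff' package reads but cannot write resolution
# tags, which this package needs to preserve calibration; written files are
# verified against libtiff (tiff::readTIFF) in the test suite.
# mode: "float32" or "uint16"
.write_tiff <- function(channels, path, pixel_size_um, mode) {
  nchan <- length(channels)
  H <- nrow(channels[[1]]); W <- ncol(channels[[1]])
  rr <- .res_rational(pixel_size_um)
  bps <- if (mode == "float32") 32L else 16L
  sfmt <- if (mode == "float32") 3L else 1L
  bytes_px <- bps / 8L
  strip_len <- H * W * bytes_px
  ntags <- 13L
  ifd_len <- 2L + ntags * 12L + 4L
  # per page: IFD, then 2 rationals (16 bytes), then strip data
  page_block <- ifd_len + 16L + strip_len
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)
  for (k in seq_len(nchan)) {
    base <- 8L + (k - 1L) * page_block
    rat_off <- base + ifd_len
    strip_off <- rat_off + 16L
    next_ifd <- if (k < nchan) base + page_block else 0L
    tag <- function(id, type, count, value) {
      w2(id); w2(type); w4(count)
      if (type == 3 && count == 1) { w2(value); w2(0L) } else w4(value)
    }
    w2(ntags)
    tag(256L, 3L, 1L, W)            # ImageWidth
    tag(257L, 3L, 1L, H)            # ImageLength
    tag(258L, 3L, 1L, bps)          # BitsPerSample
    tag(259L, 3L, 1L, 1L)           # Compression: none
    tag(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    tag(273L, 4L, 1L, strip_off)    # StripOffsets
    tag(277L, 3L, 1L, 1L)           # SamplesPerPixel
    tag(278L, 3L, 1L, H)            # RowsPerStrip
    tag(279L, 4L, 1L, strip_len)    # StripByteCounts
    tag(282L, 5L, 1L, rat_off)      # XResolution
    tag(283L, 5L, 1L, rat_off + 8L) # YResolution
    tag(296L, 3L, 1L, 3L)           # ResolutionUnit: cm
    tag(339L, 3L, 1L, sfmt)         # SampleFormat
    w4(next_ifd)
    w4(rr["num"]); w4(rr["den"]); w4(rr["num"]); w4(rr["den"])
    m <- t(channels[[k]]) # strips are row-major
    if (mode == "float32") {
      writeBin(as.numeric(m), con, size = 4, endian = "little")
    } else {
      v <- as.integer(m)
      # writeBin size=2 takes signed integers; recode the upper half
      v[v > 32767L] <- v[v > 32767L] - 65536L
      writeBin(v, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Write a calibrated image as TIFF
#'
#' Writes each channel as one 32-bit float page of an uncompressed TIFF
#' with resolution tags carrying the pixel size (pixels per centimetre).
#'
#' @param image a [calibrated_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibrated_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  .write_tiff(image$pixels, path, image$pixel_size_um, "float32")
  invisible(path)
}

#' Read an instance label map from TIFF
#'
#' @param path path to an integer-valued TIFF.
#' @param pixel_size_um optional override of the parsed pixel size
#'   (defaults to the resolution metadata, or 1 um/px).
#' @return a [label_map]. Values are checked to be integral.
#' @export
read_label_map <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) .eq_stop("file not found: ", path)
  m <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
  if (length(dim(m)) != 2) .eq_stop("label TIFF must be single-channel 2D")
  ps <- .pixel_size_from_info(attributes(m))
  if (is.na(ps)) ps <- 1.0
  if (!is.null(pixel_size_um)) ps <- pixel_size_um
  if (is.double(m) && any(m != round(m)))
    .eq_stop("label TIFF contains non-integral values")
  mm <- matrix(as.integer(round(m)), nrow(m), ncol(m))
  label_map(mm, ps)
}

#' Write an instance label map as TIFF
#'
#' Labels are stored as uncompressed 16-bit unsigned integers; the
#' write/read roundtrip is bit-exact. Maps with more than 65535 objects
#' are rejected.
#'
#' @param labels a [label_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  if (max(labels$labels) > 65535L)
    .eq_stop("more than 65535 labels cannot be stored as 16-bit TIFF")
  .write_tiff(list(labels$labels), path, labels$pixel_size_um, "uint16")
  invisible(path)
}

# ---- ImageJ ROIs -----------------------------------------------------------

#' Polygonal region of interest
#'
#' @param x,y vertex coordinates, 0-based pixel centers (x = col, y = row).
#' @param name ROI name.
#' @return an object of class `polygon_roi`.
#' @export
polygon_roi <- function(x, y, name = "roi") {
  if (length(x) != length(y) || length(x) < 3)
    .eq_stop("a polygon ROI needs at least 3 (x, y) vertices")
  # drop consecutive duplicate vertices
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  x <- x[keep]; y <- y[keep]
  if (length(x) >= 2 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  if (length(x) < 3) .eq_stop("degenerate polygon ROI")
  structure(list(name = name, x = as.numeric(x), y = as.numeric(y)),
            class = "polygon_roi")
}

#' Shoelace area of a polygon ROI
#' @param roi a [polygon_roi].
#' @return area in px^2 (vertex units).
#' @export
roi_area <- function(roi) {
  x <- roi$x; y <- roi$y
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# parse one ImageJ .roi blob (raw vector) into a polygon_roi or NULL
.parse_ij_roi <- function(raw, name) {
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    .eq_stop("not an ImageJ ROI (missing 'Iout' header): ", name)
  rd2 <- function(off) { # signed big-endian short at byte offset (0-based)
    v <- as.integer(raw[off + 1L]) * 256L + as.integer(raw[off + 2L])
    if (v > 32767L) v - 65536L else v
  }
  type <- as.integer(raw[7L])
  top <- rd2(8L); left <- rd2(10L); bottom <- rd2(12L); right <- rd2(14L)
  n <- rd2(16L); if (n < 0) n <- n + 65536L
  options <- rd2(50L)
  subpixel <- bitwAnd(options, 128L) != 0L
  if (type %in% c(0L, 7L, 8L)) { # polygon, freehand, traced
    if (64L + 4L * n > length(raw)) .eq_stop("truncated ROI: ", name)
    if (subpixel && 64L + 4L * n + 8L * n <= length(raw)) {
      # absolute corner-based float coordinates follow the integer block
      fl <- readBin(raw[(64L + 4L * n + 1L):(64L + 12L * n)], "numeric",
                    n = 2L * n, size = 4L, endian = "big")
      xf <- fl[seq_len(n)]; yf <- fl[n + seq_len(n)]
      polygon_roi(xf - 0.5, yf - 0.5, name)
    } else {
      xi <- vapply(seq_len(n), function(k) rd2(64L + 2L * (k - 1L)),
                   integer(1))
      yi <- vapply(seq_len(n), function(k) rd2(64L + 2L * n + 2L * (k - 1L)),
                   integer(1))
      # stored relative to the bounding box, corner-based -> pixel centers
      polygon_roi(left + xi - 0.5, top + yi - 0.5, name)
    }
  } else if (type == 2L) { # oval -> 64-vertex ellipse
    a <- (right - left) / 2; b <- (bottom - top) / 2
    cx <- left + a - 0.5; cy <- top + b - 0.5
    t <- 2 * pi * (seq_len(64) - 1) / 64
    polygon_roi(cx + a * cos(t), cy + b * sin(t), name)
  } else if (type == 1L) { # rectangle
    polygon_roi(c(left, right, right, left) - 0.5,
                c(top, top, bottom, bottom) - 0.5, name)
  } else {
    .eq_warn("skipping unsupported ROI type ", type, " in ", name)
    NULL
  }
}

#' Read an ImageJ ROI file or ROI zip archive
#'
#' Supports polygon, freehand, traced, rectangle and oval ROIs in the
#' ImageJ binary dialect; ovals are converted to 64-vertex polygons.
#' Unsupported ROI types are skipped with a warning. Vertex coordinates
#' are returned as 0-based pixel centers.
#'
#' @param path a single `.roi` file or a `.zip` archive of `.roi` entries.
#' @return a list of [polygon_roi] in file order.
#' @export
read_roi_archive <- function(path) {
  if (!file.exists(path)) .eq_stop("file not found: ", path)
  is_zip <- grepl("\\.zip$", path, ignore.case = TRUE)
  if (!is_zip) {
    raw <- readBin(path, "raw", file.info(path)$size)
    r <- .parse_ij_roi(raw, tools::file_path_sans_ext(basename(path)))
    return(if (is.null(r)) list() else list(r))
  }
  entries <- utils::unzip(path, list = TRUE)$Name
  ex <- file.path(tempfile("rois"), "x")
  dir.create(ex, recursive = TRUE)
  on.exit(unlink(dirname(ex), recursive = TRUE))
  utils::unzip(path, exdir = ex)
  out <- list()
  for (e in entries) {
    f <- file.path(ex, e)
    raw <- readBin(f, "raw", file.info(f)$size)
    r <- .parse_ij_roi(raw, tools::file_path_sans_ext(basename(e)))
    if (!is.null(r)) out[[length(out) + 1L]] <- r
  }
  out
}

# serialize a polygon_roi to an ImageJ .roi blob (sub-pixel float
# coordinates carried alongside the rounded integer outline)
.encode_ij_roi <- function(roi) {
  # pixel-center -> corner-based coordinates
  xf <- roi$x + 0.5; yf <- roi$y + 0.5
  xc <- as.integer(floor(xf + 0.5)); yc <- as.integer(floor(yf + 0.5))
  left <- min(xc); top <- min(yc)
  n <- length(xc)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "big")
  writeBin(charToRaw("Iout"), con)
  w2(228L)                       # version
  writeBin(as.raw(c(0L, 0L)), con) # type = 0 (polygon), unused byte
  w2(top); w2(left); w2(max(yc)); w2(max(xc))
  w2(n)
  writeBin(raw(32), con)         # x1..y2 floats, stroke width, shape size,
                                 # stroke/fill colors, subtype
  w2(128L)                       # options: SUB_PIXEL_RESOLUTION
  writeBin(raw(12), con)         # arrow bytes, arc size, position, header2
  w2(xc - left)
  w2(yc - top)
  writeBin(c(xf, yf), con, size = 4, endian = "big")
  rawConnectionValue(con)
}

# ---- minimal ZIP (store method) --------------------------------------------

# xor of two 32-bit unsigned values held as doubles
.bxor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

.crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (c %% 2 == 1) .bxor32(3988292384, c %/% 2) else c %/% 2
        }
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

# CRC-32 of a raw vector, returned as a double in [0, 2^32)
.crc32 <- function(raw) {
  tab <- .crc32_table()
  crc <- 4294967295 # all ones
  for (b in as.integer(raw)) {
    idx <- bitwXor(as.integer(crc %% 256), b)
    crc <- .bxor32(crc %/% 256, tab[idx + 1])
  }
  .bxor32(crc, 4294967295)
}

.w4u <- function(con, x) { # unsigned 32-bit little-endian from double
  b <- as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
                (x %/% 16777216) %% 256))
  writeBin(b, con)
}

# write named list of raw vectors as a stored (uncompressed) zip
.write_zip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  offs <- numeric(length(entries))
  crcs <- numeric(length(entries))
  pos <- 0
  nm <- names(entries)
  for (k in seq_along(entries)) {
    data <- entries[[k]]
    name <- charToRaw(nm[k])
    offs[k] <- pos
    crcs[k] <- .crc32(data)
    .w4u(con, 67324752) # local header signature
    w2(20L); w2(0L); w2(0L); w2(0L); w2(33L) # ver, flags, method, time, date
    .w4u(con, crcs[k]); .w4u(con, length(data)); .w4u(con, length(data))
    w2(length(name)); w2(0L)
    writeBin(name, con); writeBin(data, con)
    pos <- pos + 30 + length(name) + length(data)
  }
  cd0 <- pos
  for (k in seq_along(entries)) {
    data <- entries[[k]]
    name <- charToRaw(nm[k])
    .w4u(con, 33639248) # central directory signature
    w2(20L); w2(20L); w2(0L); w2(0L); w2(0L); w2(33L)
    .w4u(con, crcs[k]); .w4u(con, length(data)); .w4u(con, length(data))
    w2(length(name)); w2(0L); w2(0L); w2(0L); w2(0L)
    .w4u(con, 0); .w4u(con, offs[k])
    writeBin(name, con)
    pos <- pos + 46 + length(name)
  }
  .w4u(con, 101010256) # end of central directory
  w2(0L); w2(0L); w2(length(entries)); w2(length(entries))
  .w4u(con, pos - cd0); .w4u(con, cd0)
  w2(0L)
  invisible(path)
}

#' Write ROIs as an ImageJ-compatible archive
#'
#' A single ROI with a `.roi` path is written as a bare ROI file;
#' otherwise a zip archive of `.roi` entries is produced. Vertices are
#' rounded to the integer ImageJ corner grid.
#'
#' @param rois list of [polygon_roi].
#' @param path output `.roi` or `.zip` path.
#' @return `path`, invisibly.
#' @export
write_roi_archive <- function(rois, path) {
  if (inherits(rois, "polygon_roi")) rois <- list(rois)
  if (grepl("\\.roi$", path, ignore.case = TRUE)) {
    if (length(rois) != 1) .eq_stop("a .roi file holds exactly one ROI")
    writeBin(.encode_ij_roi(rois[[1]]), path)
    return(invisible(path))
  }
  blobs <- lapply(rois, .encode_ij_roi)
  nms <- vapply(seq_along(rois), function(k) {
    nm <- rois[[k]]$name
    if (is.null(nm) || nm == "" || nm == "roi") sprintf("roi_%04d", k) else nm
  }, character(1))
  names(blobs) <- paste0(make.unique(nms), ".roi")
  .write_zip(blobs, path)
  invisible(path)
}

#' Rasterize polygon ROIs into a label map
#'
#' ROI `i` is painted as label `i` (1-based, list order); where ROIs
#' overlap, the later ROI wins. A pixel is painted when its center falls
#' inside the polygon (even-odd rule). Out-of-bounds vertices are
#' effectively clipped by the raster.
#'
#' @param rois list of [polygon_roi].
#' @param shape integer `(rows, cols)` of the target raster.
#' @param pixel_size_um physical pixel size of the target raster.
#' @return a [label_map]. An empty ROI list gives an all-zero map.
#' @export
rasterize_rois <- function(rois, shape, pixel_size_um = 1.0) {
  stopifnot(length(shape) == 2)
  if (length(rois) == 0)
    return(label_map(matrix(0L, shape[1], shape[2]), pixel_size_um))
  xs <- lapply(rois, function(r) r$x)
  ys <- lapply(rois, function(r) r$y)
  lab <- cpp_rasterize_polys(xs, ys, as.integer(shape[1]),
                             as.integer(shape[2]))
  label_map(lab, pixel_size_um)
}

# ---- cell tables -----------------------------------------------------------

#' Write a cell table as CSV
#'
#' One row per cell with id, centroid (um), area (um^2), per-channel mean
#' intensities, marker flags, ganglion assignment and neighbor-count
#' columns. Values survive a read-back to at least 6 significant digits.
#'
#' @param cells a cell table (`data.frame`, see [build_cell_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Read back a cell table CSV
#' @param path CSV path written by [write_cell_table()].
#' @return a `data.frame`.
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
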