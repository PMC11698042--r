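# Baseline cell segmentation.
#
# A classical detector standing in for the deep-learning cell model:
# percentile normalization, multi-scale Laplacian-of-Gaussian blob seeds,
# marker-controlled watershed restricted to a foreground mask, then size
# filtering and boundary smoothing. External segmentations (label TIFFs,
# ImageJ ROI archives) enter the same downstream pipeline unchanged.

#' Baseline segmentation parameters
#'
#' @param pmin,pmax normalization percentiles (default 1 / 99.8).
#' @param sigma_min_um,sigma_max_um,n_sigma blob-scale range in um and the
#'   number of Laplacian-of-Gaussian scales spanning it. A cell of radius
#'   r responds most strongly near `sigma = r / sqrt(2)`.
#' @param score_threshold minimum scale-normalized blob response for a
#'   seed (plays the role of a detection "probability" cut).
#' @param min_distance_um minimum separation between seeds.
#' @param fg_threshold foreground cut on the smoothed normalized
#'   intensity.
#' @param min_area_um2,max_area_um2 size filter on final labels.
#' @param smooth_radius_um radius of the per-label morphological opening
#'   that smooths boundaries.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(pmin = 1, pmax = 99.8,
                                sigma_min_um = 3, sigma_max_um = 8,
                                n_sigma = 4,
                                score_threshold = 0.06,
                                min_distance_um = 6,
                                fg_threshold = 0.3,
                                min_area_um2 = 40, max_area_um2 = 1200,
                                smooth_radius_um = 0.6) {
  if (!(pmin >= 0 && pmin < pmax && pmax <= 100))
    .eq_stop("need 0 <= pmin < pmax <= 100")
  if (sigma_min_um > sigma_max_um) .eq_stop("sigma_min_um > sigma_max_um")
  if (min_area_um2 >= max_area_um2) .eq_stop("min_area_um2 >= max_area_um2")
  structure(list(pmin = pmin, pmax = pmax, sigma_min_um = sigma_min_um,
                 sigma_max_um = sigma_max_um, n_sigma = n_sigma,
                 score_threshold = score_threshold,
                 min_distance_um = min_distance_um,
                 fg_threshold = fg_threshold,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 smooth_radius_um = smooth_radius_um),
            class = "segmentation_params")
}

#' Percentile normalization of an intensity channel
#'
#' `(I - q_pmin) / (q_pmax - q_pmin)` clipped to `[0, 1]`. A constant
#' channel (degenerate percentiles) normalizes to all zeros with a
#' warning.
#'
#' @param channel numeric matrix.
#' @param pmin,pmax percentiles in `[0, 100]`.
#' @return numeric matrix in `[0, 1]`.
#' @export
normalize_image <- function(channel, pmin = 1, pmax = 99.8) {
  if (!is.matrix(channel) || length(channel) == 0)
    .eq_stop("'channel' must be a non-empty matrix")
  q <- stats::quantile(channel, c(pmin, pmax) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    .eq_warn("degenerate normalization percentiles; returning zeros")
    return(matrix(0, nrow(channel), ncol(channel)))
  }
  out <- (channel - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# scale-normalized Laplacian-of-Gaussian response (positive on bright blobs)
.log_response <- function(img, sigma_px) {
  sm <- .gauss_blur(img, sigma_px)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  r <- EBImage::filter2(sm, lap, boundary = "replicate")
  -sigma_px^2 * matrix(as.numeric(r), nrow(img), ncol(img))
}

.gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- EBImage::gblur(img, sigma = sigma_px, boundary = "replicate")
  matrix(as.numeric(r), nrow(img), ncol(img))
}

# greedy non-maximum suppression of candidate peaks; deterministic
# (ordered by decreasing response, ties by linear index)
.suppress_peaks <- function(rows, cols, resp, min_dist_px) {
  o <- order(-resp, rows, cols)
  rows <- rows[o]; cols <- cols[o]
  keep <- logical(length(rows))
  md2 <- min_dist_px^2
  for (k in seq_along(rows)) {
    sel <- which(keep)
    if (length(sel) == 0 ||
        all((rows[sel] - rows[k])^2 + (cols[sel] - cols[k])^2 >= md2)) {
      keep[k] <- TRUE
    }
  }
  cbind(row = rows[keep], col = cols[keep])
}

#' Segment cells with the classical baseline detector
#'
#' Pipeline: percentile normalization, multi-scale
#' Laplacian-of-Gaussian maxima as seeds (response at least
#' `score_threshold`, separation at least `min_distance_um`),
#' marker-controlled watershed on the inverted smoothed intensity
#' restricted to the foreground mask, area filtering, per-label opening
#' by `smooth_radius_um`, label compaction. Deterministic for fixed
#' input.
#'
#' @param channel numeric matrix (one intensity channel) or a
#'   [calibrated_image] (first channel used).
#' @param params a [segmentation_params].
#' @param pixel_size_um pixel size of `channel` (taken from the image if
#'   a [calibrated_image] is given).
#' @return a [label_map]; empty (all zero) when nothing exceeds the
#'   foreground threshold.
#' @export
segment_cells_baseline <- function(channel, params = segmentation_params(),
                                   pixel_size_um = NULL) {
  if (inherits(channel, "calibrated_image")) {
    if (is.null(pixel_size_um)) pixel_size_um <- channel$pixel_size_um
    channel <- channel$pixels[[1]]
  }
  if (is.null(pixel_size_um)) .eq_stop("'pixel_size_um' is required")
  stopifnot(inherits(params, "segmentation_params"))
  ps <- pixel_size_um
  norm <- normalize_image(channel, params$pmin, params$pmax)
  H <- nrow(norm); W <- ncol(norm)
  empty <- label_map(matrix(0L, H, W), ps)

  # foreground mask on a lightly smoothed image; suppresses pixel noise
  sm <- .gauss_blur(norm, 1 / ps)
  mask <- sm >= params$fg_threshold
  if (!any(mask)) return(empty)

  # multi-scale LoG seeds
  sigmas <- seq(params$sigma_min_um, params$sigma_max_um,
                length.out = max(2, params$n_sigma)) / ps
  resp <- Reduce(pmax, lapply(sigmas, function(s) .log_response(norm, s)))
  mx <- EBImage::dilate(resp, EBImage::makeBrush(3, "box"))
  is_peak <- resp >= matrix(as.numeric(mx), H, W) &
    resp >= params$score_threshold & mask
  if (!any(is_peak)) return(empty)
  idx <- which(is_peak)
  peaks <- .suppress_peaks((idx - 1L) %% H, (idx - 1L) %/% H, resp[idx],
                           params$min_distance_um / ps)
  seeds <- matrix(0L, H, W)
  seeds[cbind(peaks[, "row"] + 1L, peaks[, "col"] + 1L)] <- seq_len(nrow(peaks))

  lab <- cpp_seeded_watershed(-sm, seeds, mask)

  # size filter, then boundary smoothing by per-label opening
  lab <- filter_labels(label_map(lab, ps), params$min_area_um2,
                       params$max_area_um2)$labels
  if (params$smooth_radius_um > 0 && any(lab > 0))
    lab <- .open_labels(lab, params$smooth_radius_um / ps)
  out <- filter_labels(label_map(lab, ps), params$min_area_um2,
                       params$max_area_um2)
  out
}

# per-label binary opening (erosion then dilation by a Euclidean disc),
# computed with the exact distance transform within each label's bbox
.open_labels <- function(lab, r_px) {
  if (r_px <= 0) return(lab)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pad <- as.integer(ceiling(r_px) + 1L)
  for (l in sort(setdiff(unique(as.vector(lab)), 0L))) {
    w <- which(lab == l, arr.ind = TRUE)
    r0 <- max(1L, min(w[, 1]) - pad); r1 <- min(nrow(lab), max(w[, 1]) + pad)
    c0 <- max(1L, min(w[, 2]) - pad); c1 <- min(ncol(lab), max(w[, 2]) + pad)
    sub <- lab[r0:r1, c0:c1, drop = FALSE] == l
    # erode: keep pixels at distance > r from the complement
    dc <- cpp_edt_sq(!sub)
    core <- dc > r_px^2
    if (!any(core)) next # label vanishes under opening
    dd <- cpp_edt_sq(core)
    opened <- dd <= r_px^2 & sub
    blk <- out[r0:r1, c0:c1, drop = FALSE]
    blk[opened] <- l
    out[r0:r1, c0:c1] <- blk
  }
  out
}

#' Filter labels by area and border contact
#'
#' Removes labels whose area falls outside `[min_area_um2,
#' max_area_um2]` and, optionally, labels touching the raster border;
#' survivors are compacted to 1..n. Never increases the object count and
#' is idempotent.
#'
#' @param labels a [label_map].
#' @param min_area_um2,max_area_um2 area bounds in um^2.
#' @param exclude_edge drop labels touching the image border.
#' @return a filtered [label_map].
#' @export
filter_labels <- function(labels, min_area_um2 = 0, max_area_um2 = Inf,
                          exclude_edge = FALSE) {
  stopifnot(inherits(labels, "label_map"))
  m <- labels$labels
  if (!any(m > 0)) return(compact_labels(labels))
  ps2 <- labels$pixel_size_um^2
  tab <- tabulate(m[m > 0L])
  areas <- tab * ps2
  drop <- which(tab > 0L & (areas < min_area_um2 | areas > max_area_um2))
  if (exclude_edge) {
    edge <- unique(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
    drop <- union(drop, setdiff(edge, 0L))
  }
  if (length(drop) > 0) m[m %in% drop] <- 0L
  compact_labels(label_map(m, labels$pixel_size_um))
}

#' Build a per-cell measurement table
#'
#' One row per label with id, area-weighted centroid (um), area (um^2)
#' and per-channel mean intensity. The outer boundary of each cell
#' (ordered boundary pixel centers) is attached as the `"outlines"`
#' attribute, a list of [polygon_roi].
#'
#' @param labels a [label_map].
#' @param image a [calibrated_image] sharing shape and pixel size with
#'   `labels` (optional: omit for geometry-only tables).
#' @return a `data.frame` of class `cell_table` with attributes
#'   `outlines` and `pixel_size_um`.
#' @export
build_cell_table <- function(labels, image = NULL) {
  stopifnot(inherits(labels, "label_map"))
  labels <- compact_labels(labels)
  m <- labels$labels
  ps <- labels$pixel_size_um
  chans <- list()
  chan_names <- character(0)
  if (!is.null(image)) {
    stopifnot(inherits(image, "calibrated_image"))
    if (!all(dim(image$pixels[[1]]) == dim(m)))
      .eq_stop("label map and image shapes differ")
    if (abs(image$pixel_size_um - ps) > 1e-9 * ps)
      .eq_stop("label map and image pixel sizes differ")
    chans <- image$pixels
    chan_names <- image$channel_names
  }
  n <- n_objects(labels)
  if (n == 0) {
    df <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                     area_um2 = numeric(0))
    for (nm in chan_names) df[[paste0("mean_", nm)]] <- numeric(0)
    df$ganglion_id <- integer(0)
    attr(df, "outlines") <- list()
    attr(df, "pixel_size_um") <- ps
    class(df) <- c("cell_table", "data.frame")
    return(df)
  }
  chan_vec <- if (length(chans) == 0) numeric(0)
              else unlist(chans, use.names = FALSE)
  st <- cpp_label_stats(m, chan_vec, length(chans))
  area_px <- st$area_px
  df <- data.frame(id = seq_len(n),
                   x_um = st$sum_col / area_px * ps,
                   y_um = st$sum_row / area_px * ps,
                   area_um2 = area_px * ps^2)
  for (k in seq_along(chan_names))
    df[[paste0("mean_", chan_names[k])]] <- st$intensity_sum[, k] / area_px
  df$ganglion_id <- rep(NA_integer_, n)
  tr <- cpp_trace_boundaries(m)
  outlines <- lapply(seq_len(n), function(l) {
    v <- tr[[l]]
    if (is.null(v) || nrow(v) < 3) {
      # tiny labels: use the pixel block corners around the pixels
      w <- which(m == l, arr.ind = TRUE) - 1L
      x0 <- min(w[, 2]) - 0.4; x1 <- max(w[, 2]) + 0.4
      y0 <- min(w[, 1]) - 0.4; y1 <- max(w[, 1]) + 0.4
      polygon_roi(c(x0, x1, x1, x0), c(y0, y0, y1, y1),
                  name = sprintf("cell_%04d", l))
    } else {
      polygon_roi(v[, 1], v[, 2], name = sprintf("cell_%04d", l))
    }
  })
  attr(df, "outlines") <- outlines
  attr(df, "pixel_size_um") <- ps
  class(df) <- c("cell_table", "data.frame")
  df
}
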