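# Synthetic ganglia scenes with full ground truth.
#
# Scenes emulate Hu-labeled myenteric wholemounts: star-convex somata
# clustered into well-separated ganglia, with inter-cell edge gaps drawn
# from the empirical spacing distribution of myenteric neurons (mean
# 6.32 um, s.d. 5.17 um, truncated), cell sizes calibrated so that the
# mean soma area at the default pixel size matches the 701.2 px^2
# training-set mean, per-marker Bernoulli positivity flags, Gaussian
# optics blur and additive Gaussian noise at a stated SNR. Ground truth
# (cell labels, ganglia masks, marker flags, programmed statistics) is
# returned alongside the rendered channels.

#' Specification of a synthetic ganglia scene
#'
#' @param shape raster `(rows, cols)` in px.
#' @param pixel_size_um pixel size (default 0.568, the mouse-normalized
#'   model resolution).
#' @param n_ganglia number of ganglia.
#' @param cells_per_ganglion list `(mean, sd, min)` for the per-ganglion
#'   cell count draw.
#' @param cell_radius_um list `(mean, sd_frac, min_frac)`: base soma
#'   radius distribution. The default mean is calibrated so that the
#'   rendered mean soma area is about 701.2 px^2 at the default pixel
#'   size.
#' @param gap_um list `(mean, sd, min, max)`: edge-to-edge gap
#'   distribution between a new cell and its anchor neighbor. Truncated
#'   below at 0.5 um (avoids fused somata) and above at `mean + 2 sd`
#'   (keeps each ganglion a single spatial cluster).
#' @param marker_proportions named probabilities of marker positivity;
#'   markers are drawn independently per cell.
#' @param snr mean soma intensity divided by the background noise s.d.
#' @param blur_sigma_um Gaussian optics blur.
#' @param seed integer seed governing every draw.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(1024, 1024),
                       pixel_size_um = 0.568,
                       n_ganglia = 4,
                       cells_per_ganglion = list(mean = 14, sd = 4, min = 5),
                       cell_radius_um = list(mean = 8.63, sd_frac = 0.14,
                                             min_frac = 0.6),
                       gap_um = list(mean = 6.32, sd = 5.17, min = 0.5,
                                     max = 6.32 + 2 * 5.17),
                       marker_proportions = c(calret = 0.25, calb = 0.06),
                       snr = 10,
                       blur_sigma_um = 0.8,
                       seed = 0) {
  if (any(marker_proportions < 0 | marker_proportions > 1))
    .eq_stop("marker proportions must lie in [0, 1]")
  if (pixel_size_um <= 0) .eq_stop("'pixel_size_um' must be positive")
  structure(list(shape = as.integer(shape), pixel_size_um = pixel_size_um,
                 n_ganglia = n_ganglia,
                 cells_per_ganglion = cells_per_ganglion,
                 cell_radius_um = cell_radius_um, gap_um = gap_um,
                 marker_proportions = marker_proportions, snr = snr,
                 blur_sigma_um = blur_sigma_um, seed = seed),
            class = "scene_spec")
}

# mean of a normal truncated to [a, b]
.truncnorm_mean <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  mu + sigma * (stats::dnorm(al) - stats::dnorm(be)) / z
}

.draw_truncnorm <- function(mu, sigma, a, b) {
  repeat {
    x <- stats::rnorm(1, mu, sigma)
    if (x >= a && x <= b) return(x)
  }
}

# star-convex soma shape: base radius times a low-frequency radial
# perturbation evaluated at m knot angles
.draw_shape <- function(spec) {
  cr <- spec$cell_radius_um
  R <- .draw_truncnorm(cr$mean, cr$sd_frac * cr$mean,
                       cr$min_frac * cr$mean, Inf)
  m <- sample(8:16, 1)
  b1 <- stats::runif(1, 0, 0.08)
  b2 <- stats::runif(1, 0, 0.05)
  p1 <- stats::runif(1, 0, 2 * pi)
  p2 <- stats::runif(1, 0, 2 * pi)
  phase <- stats::runif(1, 0, 2 * pi)
  th <- phase + 2 * pi * (seq_len(m) - 1) / m
  rad <- R * (1 + b1 * cos(2 * (th - p1)) + b2 * cos(3 * (th - p2)))
  list(R = R, theta = th, rad = rad, rmax = R * (1 + b1 + b2))
}

.shape_vertices <- function(shape, pos) {
  cbind(pos[1] + shape$rad * cos(shape$theta),
        pos[2] + shape$rad * sin(shape$theta))
}

# squared distance from points to a segment (vectorized over points)
.pt_seg_d2 <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) rep(0, length(px))
       else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
}

# exact minimum distance between two simple polygons (0 when they touch
# or overlap)
.poly_min_dist <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  ja <- c(2:na, 1); jb <- c(2:nb, 1)
  best <- Inf
  for (e in seq_len(nb)) {
    best <- min(best, .pt_seg_d2(A[, 1], A[, 2], B[e, 1], B[e, 2],
                                 B[jb[e], 1], B[jb[e], 2]))
  }
  for (e in seq_len(na)) {
    best <- min(best, .pt_seg_d2(B[, 1], B[, 2], A[e, 1], A[e, 2],
                                 A[ja[e], 1], A[ja[e], 2]))
  }
  # overlap test: any vertex of one inside the other (star-convex polygons
  # placed apart; vertex containment catches interpenetration)
  inside <- function(P, Q) {
    x <- P[1]; y <- P[2]
    cr <- FALSE
    nq <- nrow(Q); j <- c(2:nq, 1)
    for (e in seq_len(nq)) {
      y0 <- Q[e, 2]; y1 <- Q[j[e], 2]
      if ((y0 <= y) != (y1 <= y)) {
        xi <- Q[e, 1] + (y - y0) * (Q[j[e], 1] - Q[e, 1]) / (y1 - y0)
        if (xi > x) cr <- !cr
      }
    }
    cr
  }
  if (inside(A[1, ], B) || inside(B[1, ], A)) return(0)
  sqrt(best)
}

# radial distance of the shape's polygon boundary along direction theta
.poly_radius <- function(shape, theta) {
  th <- shape$theta; rad <- shape$rad; m <- length(th)
  a <- (theta - th[1]) %% (2 * pi)
  step <- 2 * pi / m
  i <- min(floor(a / step), m - 1)
  t0 <- i * step; t1 <- t0 + step
  r0 <- rad[(i %% m) + 1]; r1 <- rad[((i + 1) %% m) + 1]
  # exact radial distance of the chord between the two knots
  r0 * r1 * sin(step) /
    (r0 * sin(t1 - a) + r1 * sin(a - t0))
}

# binary closing by a Euclidean disc, computed with the exact EDT
.close_mask <- function(mask, r_px) {
  d2 <- cpp_edt_sq(mask)
  dil <- d2 <= r_px^2
  d2c <- cpp_edt_sq(!dil)
  d2c > r_px^2
}

#' Generate a synthetic ganglia scene
#'
#' Deterministic for a given spec (the seed governs every draw).
#' Ganglion centers are placed by minimum-distance rejection sampling;
#' within a ganglion, each new soma is anchored to a previously placed
#' one at a drawn edge-to-edge gap (dart throwing with bounded retries),
#' so the programmed gap distribution is realized as the
#' nearest-neighbor edge distance. Ground-truth ganglia are the
#' morphological closing of each cluster (one 8-connected component per
#' ganglion), so the intra-ganglionic space between somata is part of
#' the ganglion.
#'
#' @param spec a [scene_spec].
#' @return an object of class `synthetic_scene`: fields `image`
#'   ([calibrated_image]: `hu` plus one channel per marker), `gt_cells`
#'   ([label_map]), `gt_ganglia` (`ganglia_mask`), `gt_flags`
#'   (`data.frame` of per-cell marker logicals), `cells` (placement
#'   geometry) and `truth` (programmed summaries).
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  ps <- spec$pixel_size_um
  H <- spec$shape[1]; W <- spec$shape[2]
  field_um <- c(W, H) * ps # (x, y) extent
  g <- spec$gap_um
  cr <- spec$cell_radius_um

  # cluster footprint estimate drives ganglion center placement
  n_mean <- spec$cells_per_ganglion$mean
  rg_est <- max(sqrt(n_mean) * (cr$mean * 1.2 + g$mean / 2), 3 * cr$mean)
  rg_max <- 1.35 * rg_est
  min_sep <- 2 * rg_max + 40
  margin <- rg_max + 3 * ps

  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < spec$n_ganglia) {
    if ((tries <- tries + 1) > 5000)
      .eq_stop("ganglion placement failed: 'n_ganglia' too crowded for ",
               "this shape")
    cx <- stats::runif(1, margin, field_um[1] - margin)
    cy <- stats::runif(1, margin, field_um[2] - margin)
    if (nrow(centers) == 0 ||
        all((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 >= min_sep^2))
      centers <- rbind(centers, c(cx, cy))
  }

  # per-ganglion cell counts
  cpg <- spec$cells_per_ganglion
  n_k <- vapply(seq_len(spec$n_ganglia), function(i) {
    max(cpg$min, .round_half_up(stats::rnorm(1, cpg$mean, max(cpg$sd, 0))))
  }, numeric(1))

  cells <- list()
  for (gi in seq_len(spec$n_ganglia)) {
    placed <- list()
    for (k in seq_len(n_k[gi])) {
      ok <- FALSE
      # one shape per soma: redrawing on failed attempts would bias the
      # accepted sizes downward in crowded clusters
      sh <- .draw_shape(spec)
      for (att in 1:500) {
        if (k == 1) {
          pos <- centers[gi, ]
          gap <- NA_real_
          anchor <- NA_integer_
        } else {
          anchor <- if (length(placed) == 1) 1L else sample(length(placed), 1)
          gap <- .draw_truncnorm(g$mean, g$sd, g$min, g$max)
          th <- stats::runif(1, 0, 2 * pi)
          dir <- c(cos(th), sin(th))
          d <- .poly_radius(placed[[anchor]]$shape, th) + gap +
            .poly_radius(sh, th + pi)
          va <- .shape_vertices(placed[[anchor]]$shape,
                                placed[[anchor]]$pos)
          # walk outward until the exact polygon gap equals the draw
          for (it in 1:5) {
            pos <- placed[[anchor]]$pos + d * dir
            md <- .poly_min_dist(va, .shape_vertices(sh, pos))
            if (abs(md - gap) <= 0.02 * gap) break
            d <- d + (gap - md)
          }
          if (abs(md - gap) > 0.05 * gap) next
        }
        if (sqrt(sum((pos - centers[gi, ])^2)) > rg_max) next
        if (pos[1] < sh$rmax + 2 * ps || pos[2] < sh$rmax + 2 * ps ||
            pos[1] > field_um[1] - sh$rmax - 2 * ps ||
            pos[2] > field_um[2] - sh$rmax - 2 * ps) next
        # conservative clearance from every other placed soma keeps the
        # drawn gap the realized nearest-neighbor distance
        clear <- TRUE
        if (length(placed) > 0) {
          need <- if (is.na(gap)) g$min else gap
          for (ii in seq_along(placed)) {
            if (!is.na(gap) && ii == anchor) next
            dd <- sqrt(sum((placed[[ii]]$pos - pos)^2))
            if (dd - placed[[ii]]$shape$rmax - sh$rmax < need) {
              clear <- FALSE; break
            }
          }
        }
        if (!clear) next
        placed[[k]] <- list(pos = pos, shape = sh, gap = gap,
                            anchor = anchor, ganglion = gi)
        ok <- TRUE
        break
      }
      if (!ok)
        .eq_stop("soma placement failed: 'cells_per_ganglion' or 'gap_um'",
                 " too crowded for the cluster size")
    }
    cells <- c(cells, placed)
  }
  n_cells <- length(cells)

  # per-cell intensities and marker flags
  intensity <- stats::runif(n_cells, 0.6, 1.0)
  flags <- as.data.frame(lapply(spec$marker_proportions, function(p) {
    stats::runif(n_cells) < p
  }))
  if (ncol(flags) > 0) names(flags) <- names(spec$marker_proportions)
  flags <- cbind(data.frame(id = seq_len(n_cells)), flags)

  scene <- .render_scene(spec, cells, intensity, flags)
  scene$truth <- .programmed_truth(spec, cells, flags)
  scene
}

# rasterize geometry and render channels; shared by generate and stretch
.render_scene <- function(spec, cells, intensity, flags, shape_px = NULL,
                          stretch = c(1, 1)) {
  ps <- spec$pixel_size_um
  if (is.null(shape_px)) shape_px <- spec$shape
  H <- shape_px[1]; W <- shape_px[2]
  n_cells <- length(cells)
  polys <- lapply(cells, function(cl) {
    x <- (cl$pos[1] + cl$shape$rad * cos(cl$shape$theta)) * stretch[1]
    y <- (cl$pos[2] + cl$shape$rad * sin(cl$shape$theta)) * stretch[2]
    cbind(x, y) / ps # um -> px centers
  })
  lab <- cpp_rasterize_polys(lapply(polys, function(p) p[, 1]),
                             lapply(polys, function(p) p[, 2]), H, W)
  gt_cells <- label_map(lab, ps)

  # Ground-truth ganglia, one label per cluster: the cluster cells closed
  # by a disc of half the mean edge gap (fills the usual inter-soma
  # corridors without an outer halo) united with a corridor of width equal
  # to the drawn gap along every anchor link (keeps each ganglion one
  # component and gives wide links a passage of their own width).
  gang <- matrix(0L, H, W)
  r_close <- spec$gap_um$mean / 2 / ps
  sfac <- sqrt(prod(stretch))
  gids <- vapply(cells, function(cl) cl$ganglion, numeric(1))
  for (gi in sort(unique(gids))) {
    ids <- which(gids == gi)
    # anchor corridors as rectangles between soma centers
    strip_x <- list(); strip_y <- list()
    for (ci in ids) {
      cl <- cells[[ci]]
      if (is.na(cl$anchor)) next
      an <- cells[[ids[cl$anchor]]]
      p1 <- cl$pos * stretch; p2 <- an$pos * stretch
      v <- p2 - p1
      len <- sqrt(sum(v^2))
      if (len == 0) next
      # corridor width 0.8 x gap: the passage between curved soma
      # boundaries narrows toward the cells, so the equivalent-thickness
      # rectangle is slightly narrower than the drawn edge gap
      u <- c(-v[2], v[1]) / len * (0.8 * cl$gap * sfac / 2)
      sx <- c(p1[1] + u[1], p2[1] + u[1], p2[1] - u[1], p1[1] - u[1]) / ps
      sy <- c(p1[2] + u[2], p2[2] + u[2], p2[2] - u[2], p1[2] - u[2]) / ps
      strip_x[[length(strip_x) + 1L]] <- sx
      strip_y[[length(strip_y) + 1L]] <- sy
    }
    sub <- matrix(lab %in% ids, H, W)
    if (length(strip_x) > 0) {
      strips <- cpp_rasterize_polys(strip_x, strip_y, H, W)
      sub <- sub | strips > 0L
    }
    w <- which(sub, arr.ind = TRUE)
    if (nrow(w) == 0) next
    pad <- as.integer(ceiling(r_close * 2) + 4L)
    r0 <- max(1L, min(w[, 1]) - pad); r1 <- min(H, max(w[, 1]) + pad)
    c0 <- max(1L, min(w[, 2]) - pad); c1 <- min(W, max(w[, 2]) + pad)
    blk <- sub[r0:r1, c0:c1, drop = FALSE]
    rc <- r_close
    for (rep in 1:3) { # grow the disc if the cluster stays split
      closed <- .close_mask(blk, rc)
      if (max(cpp_label_cc(closed, 8L)) <= 1L) break
      rc <- rc * 1.5
    }
    dst <- gang[r0:r1, c0:c1, drop = FALSE]
    dst[closed] <- gi
    gang[r0:r1, c0:c1] <- dst
  }
  gt_ganglia <- label_map(gang, ps)
  gt_ganglia$source <- "expansion"
  class(gt_ganglia) <- c("ganglia_mask", class(gt_ganglia))

  # channels: pan-neuronal (all cells) plus one per marker (flagged cells)
  markers <- names(spec$marker_proportions)
  paint <- function(ids) {
    img <- matrix(0, H, W)
    sel <- lab > 0L & matrix(lab %in% ids, H, W)
    img[sel] <- intensity[lab[sel]]
    img
  }
  set.seed(spec$seed %% 2147483040L + 1000L) # rendering noise stream
  sig <- spec$blur_sigma_um / ps
  noise_sd <- mean(intensity) / spec$snr
  mk_chan <- function(ids) {
    img <- paint(ids)
    if (sig > 0) img <- .gauss_blur(img, sig)
    img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
  }
  chans <- c(list(hu = mk_chan(seq_len(n_cells))),
             stats::setNames(lapply(markers, function(mn) {
               mk_chan(which(flags[[mn]]))
             }), markers))
  structure(list(image = calibrated_image(chans, ps),
                 gt_cells = gt_cells, gt_ganglia = gt_ganglia,
                 gt_flags = flags, cells = cells,
                 intensity = intensity, spec = spec, stretch = stretch),
            class = "synthetic_scene")
}

.programmed_truth <- function(spec, cells, flags) {
  cr <- spec$cell_radius_um
  g <- spec$gap_um
  er2 <- cr$mean^2 * (1 + cr$sd_frac^2)
  list(n_cells = length(cells),
       mean_area_um2 = pi * er2 * 0.987, # knot-polygon chord factor
       gap_mean_um = g$mean,
       gap_mean_truncated_um = .truncnorm_mean(g$mean, g$sd, g$min, g$max),
       marker_proportions = spec$marker_proportions)
}

#' Stretch a scene before rasterization
#'
#' Scales every soma position and outline by `(sx, sy)` and re-renders
#' the scene on a raster grown by the same factors: the synthetic
#' analogue of imaging the same tissue field under stretch. Cell
#' identities, intensities and marker flags are preserved; areas scale
#' by `sx * sy` and ganglionic density by `1 / (sx * sy)`.
#'
#' @param scene a `synthetic_scene`.
#' @param sx,sy stretch factors `>= 1`.
#' @return a new `synthetic_scene`.
#' @export
stretch_scene <- function(scene, sx, sy) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (sx < 1 || sy < 1) .eq_stop("stretch factors must be >= 1")
  shape_px <- as.integer(.round_half_up(scene$spec$shape * c(sy, sx)))
  out <- .render_scene(scene$spec, scene$cells, scene$intensity,
                       scene$gt_flags, shape_px = shape_px,
                       stretch = c(sx, sy))
  out$truth <- scene$truth
  out
}

#' Programmed-versus-realized summary of a scene
#'
#' The oracle side of every recovery test: cell count, mean soma area
#' (um^2 and px^2), mean nearest-neighbor edge gap (programmed
#' distribution mean, truncated mean, drawn anchor gaps and the gap
#' realized on the raster) and marker proportions.
#'
#' @param scene a `synthetic_scene`.
#' @return a `data.frame` with columns `quantity`, `programmed`,
#'   `realized`.
#' @export
truth_summary <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  lab <- scene$gt_cells$labels
  ps <- scene$gt_cells$pixel_size_um
  areas_px <- tabulate(lab[lab > 0L])
  drawn <- vapply(scene$cells, function(cl) cl$gap, numeric(1))
  # realized nearest-neighbor edge gap from the raster
  gr <- edge_distance_graph(scene$gt_cells,
                            spatial_config(threshold_um = 6.5,
                                           search_radius_um = 60))
  nn <- tapply(c(gr$gap_um, gr$gap_um), c(gr$i, gr$j), min)
  tr <- scene$truth
  rows <- data.frame(
    quantity = c("n_cells", "mean_area_um2", "mean_area_px2",
                 "gap_mean_um", "nn_gap_mean_um"),
    programmed = c(tr$n_cells, tr$mean_area_um2, tr$mean_area_um2 / ps^2,
                   tr$gap_mean_um, tr$gap_mean_truncated_um),
    realized = c(n_objects(scene$gt_cells),
                 mean(areas_px) * ps^2, mean(areas_px),
                 mean(drawn, na.rm = TRUE), mean(nn)))
  for (mn in names(tr$marker_proportions)) {
    rows <- rbind(rows, data.frame(
      quantity = paste0("p_", mn),
      programmed = unname(tr$marker_proportions[mn]),
      realized = mean(scene$gt_flags[[mn]])))
  }
  rows
}
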