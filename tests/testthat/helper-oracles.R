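# Independent brute-force reference implementations used as oracles.
# They share only the documented conventions with the package code, not
# its algorithms: edge gaps by all-pixel-pairs scans, local thickness by
# exhaustive disc search over all half-grid centers.

# minimum edge gap between every label pair, by scanning all pixel pairs
bf_edge_graph <- function(lm, cfg) {
  m <- lm$labels
  ps <- lm$pixel_size_um
  n <- max(m)
  px <- lapply(seq_len(n), function(l) which(m == l, arr.ind = TRUE))
  out <- data.frame(i = integer(0), j = integer(0), gap_um = numeric(0))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (nrow(px[[i]]) == 0 || nrow(px[[j]]) == 0) next
    d2 <- outer(px[[i]][, 1], px[[j]][, 1], "-")^2 +
      outer(px[[i]][, 2], px[[j]][, 2], "-")^2
    gap <- max(0, sqrt(min(d2)) - 1) * ps
    if (gap <= cfg$search_radius_um)
      out <- rbind(out, data.frame(i = i, j = j, gap_um = gap))
  }
  out
}

# exhaustive local thickness: for every half-grid center, radius = exact
# distance to the nearest background pixel square, then paint every
# covered pixel; no ridge pruning, no separable transform
bf_local_thickness <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  PH <- H + 2; PW <- W + 2
  DH <- 2 * PH - 1; DW <- 2 * PW - 1
  sites <- matrix(FALSE, DH, DW)
  for (pi in 0:(PH - 1)) for (pj in 0:(PW - 1)) {
    fg <- (pi >= 1 && pi <= H && pj >= 1 && pj <= W) && mask[pi, pj]
    if (!fg) {
      for (da in -1:1) for (db in -1:1) {
        aa <- 2 * pi + da; bb <- 2 * pj + db
        if (aa >= 0 && aa < DH && bb >= 0 && bb < DW)
          sites[aa + 1, bb + 1] <- TRUE
      }
    }
  }
  sw <- which(sites, arr.ind = TRUE) - 1L
  LT <- matrix(0, H, W)
  for (a in 0:(DH - 1)) {
    d2a <- (sw[, 1] - a)^2
    for (b in 0:(DW - 1)) {
      d2 <- min(d2a + (sw[, 2] - b)^2)
      if (d2 <= 0) next
      rt <- sqrt(d2)
      rlo <- max(0, ceiling((a - rt) / 2) - 1)
      rhi <- min(H - 1, floor((a + rt) / 2) - 1)
      clo <- max(0, ceiling((b - rt) / 2) - 1)
      chi <- min(W - 1, floor((b + rt) / 2) - 1)
      if (rhi < rlo || chi < clo) next
      for (pr in rlo:rhi) for (pc in clo:chi) {
        q <- (2 * (pr + 1) - a)^2 + (2 * (pc + 1) - b)^2
        if (q <= d2 && rt > LT[pr + 1, pc + 1]) LT[pr + 1, pc + 1] <- rt
      }
    }
  }
  LT
}

# random blobby label scene for oracle-equivalence tests
random_label_scene <- function(H, W, frac = 0.75) {
  x <- matrix(stats::runif(H * W), H, W)
  sm <- enteroquant:::.gauss_blur(x, 2)
  mask <- sm > stats::quantile(sm, frac)
  label_map(enteroquant:::cpp_label_cc(mask, 8L), 1.0)
}

# rendered Gaussian blob field with additive noise (SNR = peak / sd)
render_blobs <- function(H, W, centers_px, sigma_px, snr = 10,
                         seed = 1, amp = 1) {
  set.seed(seed)
  img <- matrix(0, H, W)
  rr <- matrix(rep(0:(H - 1), W), H, W)
  cc <- matrix(rep(0:(W - 1), each = H), H, W)
  for (k in seq_len(nrow(centers_px))) {
    img <- img + amp * exp(-((rr - centers_px[k, 1])^2 +
                               (cc - centers_px[k, 2])^2) /
                             (2 * sigma_px^2))
  }
  img + matrix(stats::rnorm(H * W, 0, amp / snr), H, W)
}
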