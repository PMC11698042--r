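# Proximal-neighbor (PN) spatial analysis.
#
# Two cells are proximal neighbors when their edge-to-edge gap is at
# most a threshold T (default 6.5 um, the mean inter-neuron edge
# distance in myenteric ganglia rounded up to the next 0.5 um). The gap
# convention is the minimum boundary pixel-center distance minus one
# pixel, clamped at zero, so 4-adjacent labels touch (gap 0) and the
# value tracks physical edge separation to within half a pixel. Because
# tissue stretch rescales all distances only mildly relative to T, PN
# counts are robust to stretch while raw densities are not.

#' Spatial analysis configuration
#'
#' @param threshold_um neighbor threshold T in um (default 6.5). A pair
#'   with gap exactly T counts as neighbors (inclusive rule).
#' @param search_radius_um radius within which pair distances are stored
#'   (default `4 * threshold_um`); must be at least `threshold_um`.
#' @return an object of class `spatial_config`.
#' @export
spatial_config <- function(threshold_um = 6.5,
                           search_radius_um = 4 * threshold_um) {
  if (!(threshold_um > 0)) .eq_stop("'threshold_um' must be positive")
  if (search_radius_um < threshold_um)
    .eq_stop("'search_radius_um' must be >= 'threshold_um'")
  structure(list(threshold_um = threshold_um,
                 search_radius_um = search_radius_um),
            class = "spatial_config")
}

#' Edge-to-edge distance graph between cells
#'
#' For every pair of labels whose boundaries come within
#' `search_radius_um`, the gap `max(0, min boundary pixel-center
#' distance - 1 px) * pixel_size_um`. The sparse graph is symmetric with
#' no self-pairs.
#'
#' @param cell_labels a [label_map].
#' @param config a [spatial_config].
#' @return a `data.frame` of class `edge_distance_graph` with columns
#'   `i`, `j` (label ids, `i < j`) and `gap_um`, and attributes
#'   `n_cells` and `search_radius_um`.
#' @export
edge_distance_graph <- function(cell_labels, config = spatial_config()) {
  stopifnot(inherits(cell_labels, "label_map"),
            inherits(config, "spatial_config"))
  ps <- cell_labels$pixel_size_um
  n <- n_objects(cell_labels)
  if (n < 2) {
    g <- data.frame(i = integer(0), j = integer(0), gap_um = numeric(0))
  } else {
    max_dist_px <- config$search_radius_um / ps + 1
    g <- cpp_label_gaps(cell_labels$labels, max_dist_px)
    g <- data.frame(i = g$i, j = g$j,
                    gap_um = pmax(0, g$dist_px - 1) * ps)
    g <- g[g$gap_um <= config$search_radius_um, , drop = FALSE]
    rownames(g) <- NULL
  }
  attr(g, "n_cells") <- n
  attr(g, "search_radius_um") <- config$search_radius_um
  class(g) <- c("edge_distance_graph", "data.frame")
  g
}

#' Proximal-neighbor counts per cell
#'
#' `k_i` is the number of cells whose gap to cell `i` is at most the
#' threshold (inclusive).
#'
#' @param graph an [edge_distance_graph()] built with `search_radius >=
#'   threshold`.
#' @param config a [spatial_config].
#' @return integer vector of neighbor counts, one per cell.
#' @export
pn_counts <- function(graph, config = spatial_config()) {
  n <- attr(graph, "n_cells")
  if (is.null(n)) .eq_stop("not an edge_distance_graph")
  if (attr(graph, "search_radius_um") < config$threshold_um)
    .eq_stop("graph search radius is below the neighbor threshold")
  sel <- graph$gap_um <= config$threshold_um
  tabulate(c(graph$i[sel], graph$j[sel]), nbins = n)
}

#' Histogram of proximal-neighbor counts
#'
#' Raw counts of cells per neighbor count k = 0..max(k), optionally
#' normalized by the total cell count (bins then sum to 1).
#'
#' @param counts integer vector from [pn_counts()] or [cross_type_pn()]
#'   (`NA` entries — non-center cells — are dropped).
#' @param normalize divide bins by the number of cells.
#' @return named numeric vector over k = 0..max(k).
#' @export
pn_histogram <- function(counts, normalize = FALSE) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0) .eq_stop("no counts to histogram")
  h <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  names(h) <- as.character(seq_along(h) - 1L)
  if (normalize) h / sum(h) else h
}

#' Cross-type proximal-neighbor counts
#'
#' For each center cell (rows of `flags_center`), the number of
#' neighbors within the threshold that satisfy `flags_neighbor`. With
#' all-true flags this reduces to [pn_counts()].
#'
#' @param graph an [edge_distance_graph()].
#' @param flags_neighbor logical vector over cells: which cells count as
#'   neighbors.
#' @param flags_center logical vector over cells: which cells are
#'   centers (default all).
#' @param config a [spatial_config].
#' @return integer vector over all cells; `NA` for non-center cells.
#' @export
cross_type_pn <- function(graph, flags_neighbor, flags_center = NULL,
                          config = spatial_config()) {
  n <- attr(graph, "n_cells")
  if (is.null(n)) .eq_stop("not an edge_distance_graph")
  if (length(flags_neighbor) != n)
    .eq_stop("'flags_neighbor' must have one entry per cell")
  if (is.null(flags_center)) flags_center <- rep(TRUE, n)
  if (length(flags_center) != n)
    .eq_stop("'flags_center' must have one entry per cell")
  if (!any(flags_center)) .eq_stop("no center cells")
  sel <- graph$gap_um <= config$threshold_um
  i <- graph$i[sel]; j <- graph$j[sel]
  # i's neighbor j counts when j is flagged, and vice versa
  k <- tabulate(c(i[flags_neighbor[j]], j[flags_neighbor[i]]), nbins = n)
  k[!flags_center] <- NA_integer_
  k
}

#' Neighbor count map
#'
#' Paints every cell with its neighbor count; background pixels carry
#' the sentinel -1, distinct from cells with k = 0.
#'
#' @param cell_labels a [label_map].
#' @param counts integer vector with one count per label.
#' @return numeric matrix (same shape) of k values with background -1.
#' @export
neighbor_count_map <- function(cell_labels, counts) {
  stopifnot(inherits(cell_labels, "label_map"))
  m <- cell_labels$labels
  n <- n_objects(cell_labels)
  if (length(counts) < n || anyNA(counts[seq_len(n)]))
    .eq_stop("missing neighbor count for a label")
  out <- matrix(-1, nrow(m), ncol(m))
  sel <- m > 0L
  out[sel] <- counts[m[sel]]
  out
}

#' Local thickness of a binary mask
#'
#' The local thickness at a pixel is the diameter (um) of the largest
#' disc that lies fully inside the mask and covers the pixel. Candidate
#' disc centers live on the half-integer pixel grid and the admissible
#' radius at a center is the exact Euclidean distance to the nearest
#' background pixel center minus half a pixel (pixels outside the image
#' count as background), so an isolated single pixel has thickness one
#' pixel.
#'
#' @param mask logical matrix.
#' @param pixel_size_um physical pixel size.
#' @return numeric matrix of thickness values in um; 0 on background.
#' @export
local_thickness <- function(mask, pixel_size_um = 1.0) {
  if (!is.matrix(mask)) .eq_stop("'mask' must be a matrix")
  mode(mask) <- "logical"
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  cpp_local_thickness(mask) * pixel_size_um
}

#' Estimate the neighbor threshold from inter-cell spacing
#'
#' Computes the local thickness of the intra-ganglionic space between
#' cells (`ganglia AND NOT cells`) and summarizes it as mean and
#' standard deviation over all region pixels; the suggested threshold is
#' the mean rounded up to the next 0.5 um (e.g. a mean spacing of 6.32
#' um suggests T = 6.5 um).
#'
#' @param cell_labels a [label_map] of cells.
#' @param ganglia_mask a `ganglia_mask` aligned with `cell_labels`.
#' @return list with `mean_um`, `sd_um`, `n_pixels` and
#'   `suggested_threshold_um`.
#' @export
estimate_threshold <- function(cell_labels, ganglia_mask) {
  stopifnot(inherits(cell_labels, "label_map"),
            inherits(ganglia_mask, "ganglia_mask"))
  if (!all(dim(cell_labels$labels) == dim(ganglia_mask$labels)))
    .eq_stop("cell and ganglia rasters differ in shape")
  region <- ganglia_mask$labels > 0L & cell_labels$labels == 0L
  if (!any(region))
    .eq_stop("no intra-ganglionic space between cells to measure")
  lt <- local_thickness(region, cell_labels$pixel_size_um)
  v <- lt[region]
  m <- mean(v)
  list(mean_um = m, sd_um = stats::sd(v), n_pixels = length(v),
       suggested_threshold_um = ceiling(m / 0.5) * 0.5)
}
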