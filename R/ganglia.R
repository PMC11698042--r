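# Ganglia delineation and per-ganglion statistics.
#
# Ganglia are delineated either by expanding the neuronal outlines by a
# user-specified distance (the default expansion, half the mean cell
# equivalent diameter, merges two cells exactly when their edge-to-edge
# gap is smaller than one cell diameter — the demarcation convention for
# closely apposed ganglionic structures), or by thresholding an external
# ganglia probability map, or by importing a segmentation.

#' Delineate ganglia by expanding cell outlines
#'
#' Every cell mask is dilated by a Euclidean disc of radius `expand_um`
#' (computed with an exact distance transform, so there are no
#' connectivity artifacts from iterated structuring elements); the union
#' is split into 8-connected components. Two cells end up in one
#' ganglion exactly when their edge gap is below `2 * expand_um`; at a
#' gap of exactly twice the radius the dilated outlines are tangent and
#' count as one component.
#'
#' @param cell_labels a [label_map] of cells.
#' @param expand_um expansion radius in um; the default (`NULL`) uses
#'   half of the mean cell equivalent diameter of the map.
#' @return a `ganglia_mask`: a [label_map] with an additional `source`
#'   field (`"expansion"`).
#' @export
ganglia_by_expansion <- function(cell_labels, expand_um = NULL) {
  stopifnot(inherits(cell_labels, "label_map"))
  ps <- cell_labels$pixel_size_um
  m <- cell_labels$labels
  if (!any(m > 0)) {
    g <- label_map(matrix(0L, nrow(m), ncol(m)), ps)
    g$source <- "expansion"
    class(g) <- c("ganglia_mask", class(g))
    return(g)
  }
  if (is.null(expand_um)) {
    areas <- tabulate(m[m > 0L]) * ps^2
    areas <- areas[areas > 0]
    expand_um <- mean(2 * sqrt(areas / pi)) / 2
  }
  if (expand_um < 0) .eq_stop("'expand_um' must be >= 0")
  r_px <- expand_um / ps
  d2 <- cpp_edt_sq(m > 0L)
  dil <- d2 <= r_px^2
  lab <- cpp_label_cc(dil, 8L)
  g <- label_map(lab, ps)
  g$source <- "expansion"
  g$expand_um <- expand_um
  class(g) <- c("ganglia_mask", class(g))
  g
}

#' Delineate ganglia from a probability map
#'
#' Binarizes an externally produced ganglia probability map at
#' `threshold` (inclusive), removes components smaller than
#' `min_area_um2` and labels the survivors (8-connected).
#'
#' @param prob_map numeric matrix with values in `[0, 1]`.
#' @param threshold probability cut, default 0.8.
#' @param min_area_um2 minimum component area kept.
#' @param pixel_size_um pixel size of the map.
#' @return a `ganglia_mask` with `source = "probability"`.
#' @export
ganglia_from_probability <- function(prob_map, threshold = 0.8,
                                     min_area_um2 = 0, pixel_size_um = 1.0) {
  if (!is.matrix(prob_map)) .eq_stop("'prob_map' must be a matrix")
  if (any(prob_map < 0 | prob_map > 1, na.rm = TRUE))
    .eq_stop("probability values must lie in [0, 1]")
  lab <- cpp_label_cc(prob_map >= threshold, 8L)
  g <- filter_labels(label_map(lab, pixel_size_um),
                     min_area_um2 = min_area_um2)
  g$source <- "probability"
  class(g) <- c("ganglia_mask", class(g))
  g
}

#' Wrap an imported label map as a ganglia mask
#' @param labels a [label_map] of ganglion instances.
#' @return a `ganglia_mask` with `source = "imported"`.
#' @export
ganglia_from_labels <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  g <- compact_labels(labels)
  g$source <- "imported"
  class(g) <- c("ganglia_mask", class(g))
  g
}

#' Assign cells to ganglia by maximal overlap
#'
#' Each cell is assigned to the ganglion its pixels overlap most; ties
#' break toward the lowest ganglion id; cells with no overlap stay
#' unassigned (`NA`).
#'
#' @param cells a cell table (see [build_cell_table()]).
#' @param cell_labels the [label_map] the table was built from.
#' @param ganglia_mask a `ganglia_mask` sharing shape and calibration.
#' @return `cells` with the `ganglion_id` column filled.
#' @export
assign_cells <- function(cells, cell_labels, ganglia_mask) {
  stopifnot(inherits(cell_labels, "label_map"),
            inherits(ganglia_mask, "ganglia_mask"))
  if (!all(dim(cell_labels$labels) == dim(ganglia_mask$labels)))
    .eq_stop("cell and ganglia rasters differ in shape")
  cl <- cell_labels$labels
  gl <- ganglia_mask$labels
  sel <- cl > 0L & gl > 0L
  cells$ganglion_id <- rep(NA_integer_, nrow(cells))
  if (any(sel)) {
    ov <- table(cell = cl[sel], ganglion = gl[sel])
    cid <- as.integer(rownames(ov))
    # which.max on a row returns the first (= lowest ganglion id) maximum
    gid <- as.integer(colnames(ov))[apply(ov, 1, which.max)]
    cells$ganglion_id[match(cid, cells$id)] <- gid
  }
  cells
}

#' Per-ganglion counts, areas and summary statistics
#'
#' @param cells a cell table with `ganglion_id` filled by
#'   [assign_cells()].
#' @param ganglia_mask the `ganglia_mask` used for assignment.
#' @return a list with `per_ganglion` (`data.frame`: id, area_um2,
#'   n_cells) and `summary` (n_ganglia, mean and median cells per
#'   ganglion, total ganglionic area in um^2, and neurons per mm^2 of
#'   ganglionic area).
#' @export
ganglia_stats <- function(cells, ganglia_mask) {
  stopifnot(inherits(ganglia_mask, "ganglia_mask"))
  gl <- ganglia_mask$labels
  ps2 <- ganglia_mask$pixel_size_um^2
  ng <- n_objects(ganglia_mask)
  if (ng == 0) {
    return(list(per_ganglion = data.frame(id = integer(0),
                                          area_um2 = numeric(0),
                                          n_cells = integer(0)),
                summary = list(n_ganglia = 0L, mean_cells = NA_real_,
                               median_cells = NA_real_,
                               total_area_um2 = 0,
                               neurons_per_mm2 = NA_real_)))
  }
  area <- tabulate(gl[gl > 0L], nbins = ng) * ps2
  cnt <- tabulate(cells$ganglion_id[!is.na(cells$ganglion_id)], nbins = ng)
  per <- data.frame(id = seq_len(ng), area_um2 = area, n_cells = cnt)
  total_area <- sum(area)
  assigned <- sum(cnt)
  list(per_ganglion = per,
       summary = list(n_ganglia = ng,
                      mean_cells = mean(cnt),
                      median_cells = stats::median(cnt),
                      total_area_um2 = total_area,
                      neurons_per_mm2 = assigned / (total_area / 1e6)))
}
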