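# Neurochemical marker positivity.
#
# A cell is called positive for a marker either by overlap with a
# subtype segmentation (default when one is available: at least a
# fraction f of the cell's pixels covered, f = 0.5) or, when only an
# intensity channel exists, by comparing the cell's mean intensity with
# a robust background threshold (median + k * MAD of non-cell pixels).

#' Marker positivity by overlap with a subtype segmentation
#'
#' A cell is positive when the fraction of its pixels covered by any
#' subtype label is at least `f`.
#'
#' @param cells a cell table.
#' @param cell_labels the [label_map] the table was built from.
#' @param subtype_labels a [label_map] (or binary matrix) of the marker
#'   segmentation, aligned with `cell_labels`.
#' @param f coverage fraction in `(0, 1]`, default 0.5.
#' @return logical vector of flags, one per cell.
#' @export
positive_by_overlap <- function(cells, cell_labels, subtype_labels,
                                f = 0.5) {
  stopifnot(inherits(cell_labels, "label_map"))
  sub <- if (inherits(subtype_labels, "label_map")) subtype_labels$labels
         else subtype_labels
  if (!all(dim(cell_labels$labels) == dim(sub)))
    .eq_stop("cell and subtype rasters differ in shape")
  if (!(f > 0 && f <= 1)) .eq_stop("'f' must be in (0, 1]")
  cl <- cell_labels$labels
  n <- nrow(cells)
  if (n == 0) return(logical(0))
  area <- tabulate(cl[cl > 0L], nbins = max(cells$id))
  cov <- tabulate(cl[cl > 0L & sub > 0L], nbins = max(cells$id))
  flags <- (cov[cells$id] / pmax(area[cells$id], 1L)) >= f
  flags
}

#' Marker positivity by intensity over robust background
#'
#' Background level and scale are the median and median absolute
#' deviation of the non-cell pixels of the marker channel; a cell is
#' positive when its mean intensity is at least `background + k *
#' scale`.
#'
#' @param cells a cell table.
#' @param cell_labels the [label_map] the table was built from.
#' @param channel numeric matrix of the marker channel.
#' @param k robust threshold multiplier, default 3.
#' @return logical vector of flags, one per cell.
#' @export
positive_by_intensity <- function(cells, cell_labels, channel, k = 3) {
  stopifnot(inherits(cell_labels, "label_map"))
  cl <- cell_labels$labels
  if (!all(dim(cl) == dim(channel)))
    .eq_stop("cell and channel rasters differ in shape")
  bg <- channel[cl == 0L]
  if (length(bg) == 0) .eq_stop("no background pixels to estimate from")
  b <- stats::median(bg)
  s <- stats::mad(bg)
  n <- nrow(cells)
  if (n == 0) return(logical(0))
  sums <- rowsum(as.numeric(channel[cl > 0L]), cl[cl > 0L])
  cnts <- tabulate(cl[cl > 0L], nbins = max(cells$id))
  means <- as.numeric(sums)[match(cells$id, as.integer(rownames(sums)))] /
    cnts[cells$id]
  if (k == 0) means > b else means >= b + k * s
}

#' Combine marker flags and summarize proportions
#'
#' Elementwise boolean combination of two flag vectors plus a summary of
#' counts and percentages of the total cell population for each marker
#' and the combination.
#'
#' @param flags_a,flags_b logical vectors over the same cells.
#' @param op `"AND"`, `"OR"` or `"XOR"`.
#' @param names_ab names of the two markers used in the summary.
#' @return list with `flags` (combined), and `summary` — a `data.frame`
#'   of count and percent (of all cells) for marker A, marker B and the
#'   combination.
#' @export
combine_markers <- function(flags_a, flags_b, op = "AND",
                            names_ab = c("A", "B")) {
  if (length(flags_a) != length(flags_b))
    .eq_stop("flag vectors differ in length")
  comb <- switch(op,
                 AND = flags_a & flags_b,
                 OR = flags_a | flags_b,
                 XOR = xor(flags_a, flags_b),
                 .eq_stop("unknown op '", op, "'"))
  n <- length(flags_a)
  pct <- function(x) if (n == 0) NA_real_ else 100 * sum(x) / n
  summ <- data.frame(
    marker = c(names_ab, paste0(names_ab[1], "_", op, "_", names_ab[2])),
    count = c(sum(flags_a), sum(flags_b), sum(comb)),
    percent = c(pct(flags_a), pct(flags_b), pct(comb)))
  list(flags = comb, summary = summ)
}
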