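# End-to-end orchestration: configuration, the quantification run,
# multi-image aggregation and the tile-sampling experiment.

#' Run configuration
#'
#' Typed, validated configuration for [run_quantify()]. Unknown fields
#' are errors (silent typos are the main configuration hazard).
#'
#' @param species `"mouse"`, `"rat"` or `"human"` (sets the model pixel
#'   size), ignored when `target_um_per_px` is given.
#' @param target_um_per_px optional custom model pixel size.
#' @param segmentation `"baseline"` or `"import"`.
#' @param import_labels a [label_map] (or label TIFF path / ROI archive
#'   path) when `segmentation = "import"`.
#' @param seg_params a [segmentation_params].
#' @param ganglia_mode `"expand"`, `"prob"` or `"import"`.
#' @param expand_um expansion radius for `"expand"` (NULL = data-adaptive
#'   default: half the mean cell equivalent diameter).
#' @param prob_map matrix (or float TIFF path) for `"prob"`.
#' @param prob_threshold probability cut for `"prob"` mode.
#' @param import_ganglia a [label_map] / path for `"import"`.
#' @param markers list of marker rules, each a list with `name`, `mode`
#'   (`"overlap"` or `"intensity"`), and `f` (overlap fraction) or `k`
#'   (intensity multiplier), plus `subtype_labels` (map or path) for
#'   overlap mode or `channel` (channel name) for intensity mode.
#' @param spatial a [spatial_config].
#' @param out_dir optional output directory; when given, tables, label
#'   TIFFs, ROI archives and the run log are written there.
#' @param seed integer recorded in the run log (the quantification
#'   itself is deterministic).
#' @param schema config schema version (currently 1).
#' @return an object of class `run_config`.
#' @export
run_config <- function(species = "mouse", target_um_per_px = NULL,
                       segmentation = c("baseline", "import"),
                       import_labels = NULL,
                       seg_params = segmentation_params(),
                       ganglia_mode = c("expand", "prob", "import"),
                       expand_um = NULL, prob_map = NULL,
                       prob_threshold = 0.8, import_ganglia = NULL,
                       markers = list(), spatial = spatial_config(),
                       out_dir = NULL, seed = 0, schema = 1L) {
  segmentation <- match.arg(segmentation)
  ganglia_mode <- match.arg(ganglia_mode)
  if (schema != 1L) .eq_stop("unsupported config schema version: ", schema)
  if (segmentation == "import" && is.null(import_labels))
    .eq_stop("'import_labels' is required when segmentation = 'import'")
  if (ganglia_mode == "prob" && is.null(prob_map))
    .eq_stop("'prob_map' is required when ganglia_mode = 'prob'")
  if (ganglia_mode == "import" && is.null(import_ganglia))
    .eq_stop("'import_ganglia' is required when ganglia_mode = 'import'")
  for (mk in markers) {
    if (is.null(mk$name)) .eq_stop("every marker rule needs a 'name'")
    mode <- mk$mode %||% "overlap"
    if (!mode %in% c("overlap", "intensity"))
      .eq_stop("marker '", mk$name, "': unknown mode '", mode, "'")
    if (mode == "overlap" && is.null(mk$subtype_labels))
      .eq_stop("marker '", mk$name, "': overlap mode needs 'subtype_labels'")
    if (mode == "intensity" && is.null(mk$channel))
      .eq_stop("marker '", mk$name, "': intensity mode needs 'channel'")
    extra <- setdiff(names(mk), c("name", "mode", "f", "k",
                                  "subtype_labels", "channel"))
    if (length(extra) > 0)
      .eq_stop("marker '", mk$name, "': unknown field(s) ",
               paste(extra, collapse = ", "))
  }
  structure(list(species = species, target_um_per_px = target_um_per_px,
                 segmentation = segmentation, import_labels = import_labels,
                 seg_params = seg_params, ganglia_mode = ganglia_mode,
                 expand_um = expand_um, prob_map = prob_map,
                 prob_threshold = prob_threshold,
                 import_ganglia = import_ganglia, markers = markers,
                 spatial = spatial, out_dir = out_dir, seed = seed,
                 schema = schema),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from a YAML file
#'
#' Flat YAML mirroring the [run_config()] arguments; unknown keys are
#' errors.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), c("seg_params", "spatial"))
  extra <- setdiff(names(y), c(known, "threshold_um", "search_radius_um",
                               "seg"))
  if (length(extra) > 0)
    .eq_stop("unknown config key(s): ", paste(extra, collapse = ", "))
  sp <- spatial_config(threshold_um = y$threshold_um %||% 6.5,
                       search_radius_um = y$search_radius_um %||%
                         4 * (y$threshold_um %||% 6.5))
  segp <- do.call(segmentation_params, y$seg %||% list())
  args <- y[intersect(names(y), known)]
  args$spatial <- sp
  args$seg_params <- segp
  do.call(run_config, args)
}

.as_label_map <- function(x, ps) {
  if (inherits(x, "label_map")) return(x)
  if (is.character(x)) {
    if (grepl("\\.(roi|zip)$", x, ignore.case = TRUE))
      .eq_stop("ROI archives must be rasterized first; see rasterize_rois()")
    return(read_label_map(x, pixel_size_um = ps))
  }
  if (is.matrix(x)) return(label_map(x, ps))
  .eq_stop("cannot interpret label input")
}

#' Quantify one image end to end
#'
#' Stages: rescale to the model pixel size, segment (or import a
#' segmentation), delineate ganglia, assign cells, call markers, run the
#' proximal-neighbor analysis, and optionally write the output bundle
#' (cell CSV, per-ganglion CSV, PN histogram CSV, label TIFF, ganglia
#' TIFF, neighbor-count map TIFF, cell outline ROI zip, run log). Rerun
#' with the same config is bit-identical.
#'
#' @param image a [calibrated_image] or TIFF path.
#' @param config a [run_config].
#' @return a result bundle (list of class `quant_result`): `cells`,
#'   `labels`, `ganglia`, `ganglia_stats`, `graph`, `pn` (counts and
#'   raw/normalized histograms), `marker_summary`, `log`.
#' @export
run_quantify <- function(image, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  if (is.character(image)) image <- read_calibrated_image(image)
  stopifnot(inherits(image, "calibrated_image"))
  ps0 <- image$pixel_size_um
  policy <- rescale_policy(custom_target = config$target_um_per_px)
  fac <- rescale_factor(ps0, policy, config$species)
  stages <- list()

  # --- segmentation (at the model pixel size) ------------------------------
  if (config$segmentation == "baseline") {
    work <- if (abs(fac - 1) > 1e-9) resample_intensity(image, fac) else image
    lab <- segment_cells_baseline(work$pixels[[1]], config$seg_params,
                                  work$pixel_size_um)
    if (abs(fac - 1) > 1e-9)
      lab <- restore_labels(lab, dim(image$pixels[[1]]), ps0)
  } else {
    lab <- compact_labels(.as_label_map(config$import_labels, ps0))
    if (!all(dim(lab$labels) == dim(image$pixels[[1]])))
      .eq_stop("stage segment: imported labels do not match the image shape")
    lab$pixel_size_um <- ps0
  }
  stages$segment <- proc.time()[["elapsed"]] - t0

  cells <- build_cell_table(lab, image)

  # --- ganglia -------------------------------------------------------------
  gang <- switch(config$ganglia_mode,
    expand = ganglia_by_expansion(lab, config$expand_um),
    prob = {
      pm <- config$prob_map
      if (is.character(pm)) {
        img <- read_calibrated_image(pm, pixel_size_um = ps0)
        pm <- img$pixels[[1]]
      }
      ganglia_from_probability(pm, config$prob_threshold,
                               pixel_size_um = ps0)
    },
    import = {
      g <- .as_label_map(config$import_ganglia, ps0)
      g$pixel_size_um <- ps0
      ganglia_from_labels(g)
    })
  cells <- assign_cells(cells, lab, gang)
  gstats <- ganglia_stats(cells, gang)
  stages$ganglia <- proc.time()[["elapsed"]] - t0

  # --- markers -------------------------------------------------------------
  marker_names <- character(0)
  for (mk in config$markers) {
    mode <- mk$mode %||% "overlap"
    flags <- if (mode == "overlap") {
      positive_by_overlap(cells, lab,
                          .as_label_map(mk$subtype_labels, ps0),
                          f = mk$f %||% 0.5)
    } else {
      ch <- image$pixels[[mk$channel]]
      if (is.null(ch)) .eq_stop("stage markers: no channel '", mk$channel, "'")
      positive_by_intensity(cells, lab, ch, k = mk$k %||% 3)
    }
    cells[[paste0("marker_", mk$name)]] <- flags
    marker_names <- c(marker_names, mk$name)
  }
  marker_summary <- if (length(marker_names) > 0) {
    data.frame(marker = marker_names,
               count = vapply(marker_names, function(mn)
                 sum(cells[[paste0("marker_", mn)]]), numeric(1)),
               percent = vapply(marker_names, function(mn)
                 if (nrow(cells) > 0)
                   100 * sum(cells[[paste0("marker_", mn)]]) / nrow(cells)
                 else NA_real_, numeric(1)),
               row.names = NULL)
  } else NULL
  stages$markers <- proc.time()[["elapsed"]] - t0

  # --- spatial -------------------------------------------------------------
  graph <- edge_distance_graph(lab, config$spatial)
  k <- pn_counts(graph, config$spatial)
  cells$pn_all <- if (nrow(cells) > 0) k[cells$id] else integer(0)
  for (mn in marker_names) {
    fl <- cells[[paste0("marker_", mn)]]
    cells[[paste0("pn_", mn)]] <- if (nrow(cells) > 0)
      cross_type_pn(graph, fl, config = config$spatial)[cells$id]
    else integer(0)
  }
  pn <- if (nrow(cells) > 0) {
    list(counts = k, histogram = pn_histogram(k, normalize = FALSE),
         normalized = pn_histogram(k, normalize = TRUE))
  } else {
    list(counts = integer(0), histogram = NULL, normalized = NULL)
  }
  stages$spatial <- proc.time()[["elapsed"]] - t0

  log <- list(package = "enteroquant",
              version = as.character(utils::packageVersion("enteroquant")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = config$seed,
              species = config$species,
              rescale_factor = fac,
              pixel_size_um = ps0,
              threshold_um = config$spatial$threshold_um,
              n_cells = nrow(cells),
              n_ganglia = gstats$summary$n_ganglia,
              stage_seconds = stages)

  res <- structure(list(cells = cells, labels = lab, ganglia = gang,
                        ganglia_stats = gstats, graph = graph, pn = pn,
                        marker_summary = marker_summary, log = log,
                        config = config),
                   class = "quant_result")
  if (!is.null(config$out_dir)) .write_bundle(res, config$out_dir)
  res
}

# fixed-layout output bundle; partial outputs are removed on failure
.write_bundle <- function(res, dir) {
  ok <- FALSE
  created <- !dir.exists(dir)
  if (created) dir.create(dir, recursive = TRUE)
  on.exit(if (!ok && created) unlink(dir, recursive = TRUE))
  write_cell_table(res$cells, file.path(dir, "cells.csv"))
  utils::write.csv(res$ganglia_stats$per_ganglion,
                   file.path(dir, "ganglia.csv"), row.names = FALSE)
  if (!is.null(res$pn$histogram)) {
    utils::write.csv(data.frame(k = as.integer(names(res$pn$histogram)),
                                count = as.numeric(res$pn$histogram),
                                normalized = as.numeric(res$pn$normalized)),
                     file.path(dir, "pn_histogram.csv"), row.names = FALSE)
  }
  write_label_map(res$labels, file.path(dir, "cells_labels.tif"))
  write_label_map(label_map(res$ganglia$labels, res$ganglia$pixel_size_um),
                  file.path(dir, "ganglia_labels.tif"))
  if (length(res$pn$counts) > 0) {
    nm <- neighbor_count_map(res$labels, res$pn$counts)
    .write_tiff(list(nm), file.path(dir, "neighbor_count_map.tif"),
                res$labels$pixel_size_um, "float32")
  }
  outl <- attr(res$cells, "outlines")
  if (length(outl) > 0)
    write_roi_archive(outl, file.path(dir, "cell_outlines.zip"))
  writeLines(yaml::as.yaml(res$log), file.path(dir, "run_log.yaml"))
  ok <- TRUE
  invisible(dir)
}

#' Aggregate result bundles into a summary table
#'
#' One row per image (sorted by name): total cell count, ganglia counts
#' and densities, per-marker counts and percentages, and the raw and
#' total-count-normalized PN histogram columns. Bundles with different
#' marker sets are merged to the union with `NA` and a warning.
#'
#' @param bundles named list of `quant_result` (names become the image
#'   column; unnamed bundles are numbered).
#' @return a `data.frame` with one row per bundle.
#' @export
aggregate_runs <- function(bundles) {
  if (length(bundles) == 0) .eq_stop("no bundles to aggregate")
  if (inherits(bundles, "quant_result")) bundles <- list(bundles)
  nms <- names(bundles) %||% rep("", length(bundles))
  nms[nms == ""] <- sprintf("image_%03d", which(nms == ""))
  marker_sets <- lapply(bundles, function(b)
    if (is.null(b$marker_summary)) character(0) else b$marker_summary$marker)
  all_markers <- Reduce(union, marker_sets)
  if (length(unique(lapply(marker_sets, sort))) > 1)
    .eq_warn("bundles carry different marker sets; merging to the union")
  kmax <- max(c(0, vapply(bundles, function(b)
    if (is.null(b$pn$histogram)) 0L else length(b$pn$histogram) - 1L,
    integer(1))))
  rows <- lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    s <- b$ganglia_stats$summary
    row <- data.frame(image = nms[i],
                      n_cells = nrow(b$cells),
                      n_ganglia = s$n_ganglia,
                      mean_cells_per_ganglion = s$mean_cells,
                      median_cells_per_ganglion = s$median_cells,
                      ganglionic_area_um2 = s$total_area_um2,
                      neurons_per_mm2 = s$neurons_per_mm2)
    for (mn in all_markers) {
      ms <- b$marker_summary
      j <- if (is.null(ms)) integer(0) else which(ms$marker == mn)
      row[[paste0("n_", mn)]] <- if (length(j) == 1) ms$count[j] else NA
      row[[paste0("pct_", mn)]] <- if (length(j) == 1) ms$percent[j] else NA
    }
    h <- rep(0, kmax + 1)
    hn <- rep(0, kmax + 1)
    if (!is.null(b$pn$histogram)) {
      h[seq_along(b$pn$histogram)] <- b$pn$histogram
      hn[seq_along(b$pn$normalized)] <- b$pn$normalized
    }
    for (k in 0:kmax) {
      row[[paste0("pn", k)]] <- h[k + 1]
      row[[paste0("pn_norm", k)]] <- hn[k + 1]
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$image), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tile-sampling experiment
#'
#' Emulates counting neurons in sampled fields of view: the calibrated
#' bounds are partitioned into square tiles of approximately
#' `tile_area_um2` (partial edge tiles below `min_tile_area_um2` are
#' excluded), then for each of `n_repeats` draws `n_tiles` tiles are
#' sampled without replacement and the cell density estimated from them
#' is compared with the full-image density.
#'
#' @param cells a cell table (uses `x_um`, `y_um` centroids).
#' @param bounds_um `(width, height)` of the image in um.
#' @param tile_area_um2 target tile area (e.g. 775918, 338116 and 150274
#'   um^2 emulate 10x, 20x and 40x fields).
#' @param n_tiles tiles drawn per repeat.
#' @param n_repeats number of repeats (default 100).
#' @param seed RNG seed for the tile draws.
#' @param min_tile_area_um2 exclusion bound for partial edge tiles
#'   (default 60000 um^2).
#' @return list with `estimates` (density per repeat, cells/um^2),
#'   `mean_density`, `sd_density`, `full_density`, `relative_error`
#'   (of the mean, vs the in-tile full density), `n_tiles_available`.
#' @export
tile_sampling_experiment <- function(cells, bounds_um, tile_area_um2,
                                     n_tiles, n_repeats = 100, seed = 0,
                                     min_tile_area_um2 = 60000) {
  stopifnot(length(bounds_um) == 2)
  side <- sqrt(tile_area_um2)
  xs <- seq(0, bounds_um[1], by = side)
  ys <- seq(0, bounds_um[2], by = side)
  if (max(xs) < bounds_um[1]) xs <- c(xs, bounds_um[1])
  if (max(ys) < bounds_um[2]) ys <- c(ys, bounds_um[2])
  tiles <- expand.grid(ix = seq_len(length(xs) - 1),
                       iy = seq_len(length(ys) - 1))
  tiles$x0 <- xs[tiles$ix]; tiles$x1 <- xs[tiles$ix + 1]
  tiles$y0 <- ys[tiles$iy]; tiles$y1 <- ys[tiles$iy + 1]
  tiles$area <- (tiles$x1 - tiles$x0) * (tiles$y1 - tiles$y0)
  tiles <- tiles[tiles$area >= min_tile_area_um2, , drop = FALSE]
  if (nrow(tiles) == 0) .eq_stop("no tiles satisfy the area bound")
  if (n_tiles > nrow(tiles))
    .eq_stop("'n_tiles' exceeds the ", nrow(tiles), " available tiles")
  # cells per tile (tiles are half-open except at the far border)
  cnt <- vapply(seq_len(nrow(tiles)), function(t) {
    sum(cells$x_um >= tiles$x0[t] &
          (cells$x_um < tiles$x1[t] | tiles$x1[t] == bounds_um[1]) &
          cells$y_um >= tiles$y0[t] &
          (cells$y_um < tiles$y1[t] | tiles$y1[t] == bounds_um[2]))
  }, numeric(1))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  est <- vapply(seq_len(n_repeats), function(r) {
    pick <- sample(nrow(tiles), n_tiles)
    sum(cnt[pick]) / sum(tiles$area[pick])
  }, numeric(1))
  full_in_tiles <- sum(cnt) / sum(tiles$area)
  list(estimates = est,
       mean_density = mean(est),
       sd_density = stats::sd(est),
       full_density = nrow(cells) / prod(bounds_um),
       in_tile_density = full_in_tiles,
       relative_error = abs(mean(est) - full_in_tiles) /
         full_in_tiles,
       n_tiles_available = nrow(tiles))
}
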