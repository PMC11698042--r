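# Shared synthetic scenes and cached summaries (generated once per test
# session; tests read numbers, not the cache).

.scene_cache <- new.env(parent = emptyenv())

# compact scene for unit tests: two ganglia in a 512 px field
small_spec <- function(seed = 0, ...) {
  scene_spec(shape = c(512, 512), n_ganglia = 2,
             cells_per_ganglion = list(mean = 8, sd = 2, min = 4),
             seed = seed, ...)
}

cached_small_scene <- function(seed = 0) {
  key <- paste0("small", seed)
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- generate_scene(small_spec(seed))
  .scene_cache[[key]]
}

# pooled statistics of 20 default scenes (seeds 0..19): ground-truth
# soma areas and the local-thickness threshold estimate per scene
default_scene_stats <- function() {
  if (is.null(.scene_cache$default_stats)) {
    areas <- c()
    lt <- c()
    for (s in 0:19) {
      sc <- generate_scene(scene_spec(seed = s))
      lab <- sc$gt_cells$labels
      areas <- c(areas, tabulate(lab[lab > 0L]))
      lt <- c(lt, estimate_threshold(sc$gt_cells, sc$gt_ganglia)$mean_um)
    }
    .scene_cache$default_stats <- list(areas_px2 = areas, lt_means = lt)
  }
  .scene_cache$default_stats
}

# marker-subtype label map derived from a scene's ground-truth flags
gt_subtype_map <- function(scene, marker) {
  m <- scene$gt_cells$labels
  keep <- scene$gt_flags$id[scene$gt_flags[[marker]]]
  m[!(m %in% keep)] <- 0L
  label_map(m, scene$gt_cells$pixel_size_um)
}
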