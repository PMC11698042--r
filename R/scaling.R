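# Pixel-size normalization.
#
# The segmentation stage assumes images normalized to a species-specific
# pixel size (mouse/rat 0.568 um/px, human 0.9 um/px) so that neuron
# somata have a uniform apparent size regardless of magnification.

#' Rescaling policy
#'
#' Target pixel sizes, in um/px, that images are normalized to before
#' segmentation: 0.568 for mouse and rat, 0.9 for human (larger somata).
#'
#' @param custom_target optional um/px target overriding the species
#'   table.
#' @return an object of class `rescale_policy` with fields `targets`
#'   (named numeric vector) and `custom_target`.
#' @export
rescale_policy <- function(custom_target = NULL) {
  targets <- c(mouse = 0.568, rat = 0.568, human = 0.9)
  if (!is.null(custom_target) &&
      (!is.numeric(custom_target) || custom_target <= 0))
    .eq_stop("'custom_target' must be a positive pixel size in um/px")
  structure(list(targets = targets, custom_target = custom_target),
            class = "rescale_policy")
}

#' Rescaling factor to the model pixel size
#'
#' The dimensionless resampling factor taking an image at
#' `pixel_size_um` to the policy target: `factor = pixel_size_um /
#' target`. Resampled dimensions are `round(dim * factor)`
#' (half-away-from-zero).
#'
#' @param pixel_size_um native pixel size, um/px.
#' @param policy a [rescale_policy].
#' @param species one of the policy's species names; ignored when the
#'   policy carries a `custom_target`.
#' @return the scalar factor.
#' @export
rescale_factor <- function(pixel_size_um, policy = rescale_policy(),
                           species = "mouse") {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    .eq_stop("'pixel_size_um' must be positive")
  target <- if (!is.null(policy$custom_target)) {
    policy$custom_target
  } else {
    if (!species %in% names(policy$targets))
      .eq_stop("unknown species '", species,
               "' and no custom target pixel size set")
    policy$targets[[species]]
  }
  pixel_size_um / target
}

# round half away from zero (R's round() is banker's rounding)
.round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Resample an intensity image by a scale factor
#'
#' Bilinear interpolation; the output pixel size is `pixel_size_um /
#' factor`, so resampling with [rescale_factor()] lands exactly on the
#' policy target. A factor of 1 returns the image unchanged.
#'
#' @param image a [calibrated_image].
#' @param factor positive scale factor (output dims = `round(dim *
#'   factor)`, half away from zero).
#' @return a [calibrated_image] at the new size.
#' @export
resample_intensity <- function(image, factor) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!is.numeric(factor) || factor <= 0) .eq_stop("'factor' must be > 0")
  if (factor == 1) return(image)
  d <- dim(image$pixels[[1]])
  nd <- .round_half_up(d * factor)
  if (any(nd < 1)) .eq_stop("rescaled image would have a zero dimension")
  chans <- lapply(image$pixels, function(m) {
    r <- EBImage::resize(m, w = nd[1], h = nd[2], filter = "bilinear")
    matrix(as.numeric(r), nd[1], nd[2])
  })
  calibrated_image(chans, image$pixel_size_um / factor,
                   image$channel_names)
}

#' Restore a label map to the native image resolution
#'
#' Nearest-neighbor resampling back to the original shape, preserving
#' label identities (no interpolation between labels). Used to report
#' segmentations obtained at the model pixel size on the original image
#' grid.
#'
#' @param labels a [label_map] produced at the rescaled size.
#' @param original_shape integer `(rows, cols)` of the native image.
#' @param original_pixel_size_um native pixel size for the restored map.
#' @return a [label_map] with shape `original_shape`.
#' @export
restore_labels <- function(labels, original_shape,
                           original_pixel_size_um = NULL) {
  stopifnot(inherits(labels, "label_map"), length(original_shape) == 2)
  d <- dim(labels$labels)
  if (is.null(original_pixel_size_um)) {
    original_pixel_size_um <- labels$pixel_size_um * d[1] / original_shape[1]
  }
  if (all(d == original_shape))
    return(label_map(labels$labels, original_pixel_size_um))
  r <- EBImage::resize(labels$labels, w = original_shape[1],
                       h = original_shape[2], filter = "none")
  m <- matrix(as.integer(r), original_shape[1], original_shape[2])
  label_map(m, original_pixel_size_um)
}
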