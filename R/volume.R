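# Core spatial containers: CT volumes, binary masks aligned to them, and the
# invertible preprocessing geometry record.

#' CT volume
#'
#' A dense 3D scalar grid with per-axis voxel spacing in mm. Axis order is
#' (x, y, z), matching NIfTI storage order; intensities are either raw
#' Hounsfield units (\code{"HU"}) or normalized to \[0, 1\]
#' (\code{"normalized"}).
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric length-3 mm-per-voxel, all positive.
#' @param intensity_kind \code{"HU"} or \code{"normalized"}.
#' @return object of class \code{ct_volume}.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1),
                      intensity_kind = c("HU", "normalized")) {
  intensity_kind <- match.arg(intensity_kind)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all grid dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive mm values")
  if (intensity_kind == "normalized" &&
      (min(voxels) < 0 || max(voxels) > 1))
    stop("normalized volumes must have values in [0, 1]")
  structure(list(voxels = voxels, spacing = spacing,
                 intensity_kind = intensity_kind),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s, spacing (%s) mm, %s, range [%.1f, %.1f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              x$intensity_kind, min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary mask aligned to a CT volume
#'
#' @param voxels 3D array with values in \{0, 1\} (logical accepted).
#' @param spacing numeric length-3 mm-per-voxel.
#' @return object of class \code{ct_mask}.
#' @export
ct_mask <- function(voxels, spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (is.logical(voxels)) {
    v <- voxels
  } else {
    if (any(voxels != 0 & voxels != 1)) stop("mask values must be 0 or 1")
    v <- voxels != 0
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive mm values")
  structure(list(voxels = v, spacing = spacing), class = "ct_mask")
}

#' @export
print.ct_mask <- function(x, ...) {
  cat(sprintf("<ct_mask> %s, spacing (%s) mm, %d foreground voxels\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = ", "), sum(x$voxels)))
  invisible(x)
}

#' Invertible preprocessing geometry
#'
#' Records the crop box (0-based, half-open), the in-plane scale factor and
#' the original grid so a mask produced in preprocessed space can be
#' restored exactly to the original grid.
#'
#' @param original_shape integer length-3 original grid dims.
#' @param original_spacing numeric length-3 original spacing (mm).
#' @param crop_lo,crop_hi integer length-3, 0-based half-open retained box.
#' @param inplane_scale scalar factor applied to the x and y axes.
#' @return object of class \code{preprocess_record}.
#' @export
preprocess_record <- function(original_shape, original_spacing, crop_lo,
                              crop_hi, inplane_scale = 0.5) {
  original_shape <- as.integer(original_shape)
  crop_lo <- as.integer(crop_lo)
  crop_hi <- as.integer(crop_hi)
  stopifnot(length(original_shape) == 3L, length(crop_lo) == 3L,
            length(crop_hi) == 3L, length(original_spacing) == 3L)
  if (any(crop_lo >= crop_hi)) stop("crop_lo must be < crop_hi per axis")
  if (any(crop_lo < 0L) || any(crop_hi > original_shape))
    stop("crop box exceeds the original grid")
  if (inplane_scale <= 0 || inplane_scale > 1)
    stop("inplane_scale must lie in (0, 1]")
  structure(list(original_shape = original_shape,
                 original_spacing = as.numeric(original_spacing),
                 crop_lo = crop_lo, crop_hi = crop_hi,
                 inplane_scale = inplane_scale),
            class = "preprocess_record")
}

cropped_shape <- function(record) record$crop_hi - record$crop_lo

# shape after crop + in-plane resampling (what the network sees)
processed_shape <- function(record) {
  cs <- cropped_shape(record)
  c(pmax(1L, as.integer(round(cs[1:2] * record$inplane_scale))), cs[3])
}
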