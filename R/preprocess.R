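# Raw CT -> network input preprocessing and its exact inversion:
# body-mask extraction, crop to the body bounding box, in-plane
# downsampling, Hounsfield windowing, and restoration of predicted masks to
# the original grid.

#' Compute a body mask from a Hounsfield-unit volume
#'
#' Thresholds the volume (air is about -1000 HU), applies binary closing
#' with a ball structuring element, fills internal holes slice by slice and
#' keeps the largest 26-connected component, yielding a single connected
#' region covering the patient body.
#'
#' @param volume a [ct_volume()] in HU.
#' @param threshold_hu voxels above this are candidate body (default -300).
#' @param closing_radius ball radius (voxels) of the binary closing.
#' @return a [ct_mask()].
#' @export
compute_body_mask <- function(volume, threshold_hu = -300,
                              closing_radius = 3L) {
  stopifnot(inherits(volume, "ct_volume"))
  if (volume$intensity_kind != "HU")
    stop("body mask extraction expects HU intensities")
  m <- volume$voxels > threshold_hu
  if (!any(m)) stop("no voxel above ", threshold_hu,
                    " HU: empty body region")
  if (closing_radius > 0) {
    m <- .cpp_binary_morph(m, closing_radius, TRUE)
    m <- .cpp_binary_morph(m, closing_radius, FALSE, outside = TRUE)
  }
  m <- .cpp_fill_holes_slicewise(m)
  lab <- .cpp_label_components(m, 26L)
  tab <- tabulate(lab[lab > 0L])
  keep <- which.max(tab)
  m <- array(lab == keep, dim = dim(lab))
  ct_mask(m, volume$spacing)
}

mask_bbox <- function(voxels) {
  idx <- which(voxels, arr.ind = TRUE)
  list(lo = apply(idx, 2, min) - 1L,   # 0-based inclusive
       hi = apply(idx, 2, max))        # 0-based exclusive == max index
}

#' Crop a volume to the body bounding box
#'
#' Returns the tight bounding box of the body mask expanded by
#' \code{margin_vox} and clipped to the grid, together with a
#' [preprocess_record()] holding the crop geometry.
#'
#' @param volume a [ct_volume()].
#' @param body a [ct_mask()] of the same shape.
#' @param margin_vox non-negative margin in voxels.
#' @param inplane_scale recorded for later restoration (the scale applied by
#'   [resample_inplane()], not applied here).
#' @return list with elements \code{volume} (cropped [ct_volume()]) and
#'   \code{record} (a [preprocess_record()]).
#' @export
crop_to_body <- function(volume, body, margin_vox = 5L, inplane_scale = 0.5) {
  stopifnot(inherits(volume, "ct_volume"), inherits(body, "ct_mask"))
  if (!identical(dim(volume$voxels), dim(body$voxels)))
    stop("volume and body mask shapes differ")
  if (!any(body$voxels)) stop("empty body mask")
  shp <- dim(volume$voxels)
  bb <- mask_bbox(body$voxels)
  lo <- pmax(bb$lo - margin_vox, 0L)
  hi <- pmin(bb$hi + margin_vox, shp)
  rec <- preprocess_record(shp, volume$spacing, lo, hi, inplane_scale)
  v <- volume$voxels[(lo[1] + 1L):hi[1], (lo[2] + 1L):hi[2],
                     (lo[3] + 1L):hi[3], drop = FALSE]
  list(volume = ct_volume(v, volume$spacing, volume$intensity_kind),
       record = rec)
}

#' Downsample the in-plane axes
#'
#' Scales the x and y grid dimensions by \code{factor} (nearest integer,
#' minimum 1), leaving z unchanged. Spacing is updated so the physical
#' extent is preserved. Intensities are interpolated trilinearly; masks
#' (\code{nearest = TRUE}) by nearest neighbor.
#'
#' @param volume a [ct_volume()] or [ct_mask()].
#' @param factor in-plane scale in (0, 1\].
#' @param nearest force nearest-neighbor interpolation.
#' @return object of the same class as the input.
#' @export
resample_inplane <- function(volume, factor = 0.5, nearest = FALSE) {
  if (factor <= 0 || factor > 1) stop("factor must lie in (0, 1]")
  is_mask <- inherits(volume, "ct_mask")
  v <- volume$voxels
  d <- dim(v)
  nd <- c(pmax(1L, as.integer(round(d[1:2] * factor))), d[3])
  if (all(nd == d)) return(volume)
  newsp <- volume$spacing * c(d[1:2] / nd[1:2], 1)
  if (is_mask || nearest) {
    out <- .cpp_nearest_resize(array(as.double(v), dim = d), as.integer(nd))
  } else {
    x4 <- array(as.double(v), dim = c(d, 1L))
    out <- .cpp_trilinear_resize(x4, as.integer(c(nd, 1L)))
    dim(out) <- nd
  }
  if (is_mask) ct_mask(array(out != 0, dim = nd), newsp)
  else ct_volume(out, newsp, volume$intensity_kind)
}

#' Window and normalize Hounsfield intensities
#'
#' Clips to \[window\[1\], window\[2\]\] HU and maps affinely to \[0, 1\]:
#' \code{(clip(v) - window[1]) / diff(window)}. With
#' \code{mode = "signed"} the alternative \code{clip(v) / window[2]} map to
#' \[-1, 1\] is used instead.
#'
#' @param volume a [ct_volume()] in HU (a normalized volume is returned
#'   unchanged).
#' @param window HU window, default \code{c(-200, 200)}.
#' @param mode \code{"unit"} (to \[0, 1\], default) or \code{"signed"}.
#' @return a normalized [ct_volume()].
#' @export
window_normalize <- function(volume, window = c(-200, 200),
                             mode = c("unit", "signed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "ct_volume"))
  if (volume$intensity_kind == "normalized") return(volume)
  v <- pmin(pmax(volume$voxels, window[1]), window[2])
  if (mode == "unit") {
    v <- (v - window[1]) / (window[2] - window[1])
    ct_volume(v, volume$spacing, "normalized")
  } else {
    structure(list(voxels = v / window[2], spacing = volume$spacing,
                   intensity_kind = "normalized_signed"),
              class = "ct_volume")
  }
}

#' Full preprocessing of one case
#'
#' Body mask, crop with margin, in-plane downsampling and HU windowing, in
#' that order; the returned record inverts the geometry.
#'
#' @param volume a raw [ct_volume()] in HU.
#' @param label optional 3D integer array (0 background, 1 liver, 2 tumor)
#'   cropped/resampled alongside by nearest neighbor.
#' @param margin_vox crop margin.
#' @param inplane_factor in-plane scale.
#' @param window HU window.
#' @return list(volume, record, label?).
#' @export
preprocess_case <- function(volume, label = NULL, margin_vox = 5L,
                            inplane_factor = 0.5, window = c(-200, 200)) {
  body <- compute_body_mask(volume)
  cr <- crop_to_body(volume, body, margin_vox, inplane_factor)
  vol <- window_normalize(resample_inplane(cr$volume, inplane_factor),
                          window)
  out <- list(volume = vol, record = cr$record)
  if (!is.null(label)) {
    lo <- cr$record$crop_lo
    hi <- cr$record$crop_hi
    lab <- label[(lo[1] + 1L):hi[1], (lo[2] + 1L):hi[2], (lo[3] + 1L):hi[3],
                 drop = FALSE]
    nd <- processed_shape(cr$record)
    lab <- .cpp_nearest_resize(array(as.double(lab), dim = dim(lab)),
                               as.integer(nd))
    out$label <- array(as.integer(lab), dim = nd)
  }
  out
}

#' Restore a preprocessed-space mask to the original grid
#'
#' Inverts the in-plane downsampling by nearest neighbor and pastes the
#' result into the crop box of an all-zero original-shape grid.
#'
#' @param mask a [ct_mask()] on the preprocessed grid.
#' @param record the matching [preprocess_record()].
#' @return a [ct_mask()] of exactly \code{record$original_shape}.
#' @export
restore_to_original <- function(mask, record) {
  stopifnot(inherits(mask, "ct_mask"), inherits(record, "preprocess_record"))
  pshape <- processed_shape(record)
  if (!identical(dim(mask$voxels), as.integer(pshape)))
    stop("mask shape (", paste(dim(mask$voxels), collapse = "x"),
         ") does not match the recorded preprocessed shape (",
         paste(pshape, collapse = "x"), ")")
  cs <- cropped_shape(record)
  up <- .cpp_nearest_resize(array(as.double(mask$voxels),
                                  dim = dim(mask$voxels)), as.integer(cs))
  out <- array(FALSE, dim = record$original_shape)
  lo <- record$crop_lo
  hi <- record$crop_hi
  out[(lo[1] + 1L):hi[1], (lo[2] + 1L):hi[2], (lo[3] + 1L):hi[3]] <- up != 0
  ct_mask(out, record$original_spacing)
}
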