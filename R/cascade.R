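# Two-stage cascaded inference: liver localization on the preprocessed
# volume, largest-component post-processing, ROI-restricted tumor
# segmentation, containment clamping and restoration to original space.

#' Keep only the largest connected component
#'
#' @param mask binary 3D array or [ct_mask()].
#' @param connectivity 26 (default) or 6.
#' @return object of the same kind as the input; an empty mask passes
#'   through unchanged.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  m <- as_mask_array(mask)
  if (!any(m)) return(mask)
  lab <- .cpp_label_components(m, as.integer(connectivity))
  tab <- tabulate(lab[lab > 0L])
  keep <- array(lab == which.max(tab), dim = dim(m))
  if (inherits(mask, "ct_mask")) ct_mask(keep, mask$spacing) else keep
}

#' Bounding box of the liver region of interest
#'
#' Tight box around the liver mask, expanded by \code{margin_vox} and
#' clipped to the grid; 0-based, half-open.
#'
#' @param liver nonempty binary 3D array or [ct_mask()].
#' @param margin_vox margin in voxels.
#' @return list(lo, hi) of integer length-3 vectors.
#' @export
liver_roi <- function(liver, margin_vox = 10L) {
  m <- as_mask_array(liver)
  if (!any(m)) stop("empty liver mask: no ROI")
  bb <- mask_bbox(m)
  list(lo = as.integer(pmax(bb$lo - margin_vox, 0L)),
       hi = as.integer(pmin(bb$hi + margin_vox, dim(m))))
}

pad_to <- function(arr, target) {
  d <- dim(arr)
  pad <- pmax(target - d, 0L)
  lo <- pad %/% 2L
  out <- array(0, dim = d + pad)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <-
    arr
  list(arr = out, lo = lo, orig = d)
}

tile_starts <- function(n, patch, stride) {
  if (n <= patch) return(0L)
  s <- seq(0L, n - patch, by = stride)
  if (s[length(s)] != n - patch) s <- c(s, n - patch)
  as.integer(s)
}

#' Sliding-window probability prediction
#'
#' Tiles the volume with overlapping patches, runs the network on each and
#' averages the sigmoid probabilities of the final output uniformly over
#' overlaps. Volumes smaller than the patch are zero-padded symmetrically
#' and cropped back. Deterministic for fixed weights and tiling.
#'
#' @param net a \code{segnet}.
#' @param volume 3D array of normalized intensities.
#' @param patch_size integer length-3; each dim divisible by 8.
#' @param overlap fraction of patch overlap in \[0, 1).
#' @return 3D array of probabilities in \[0, 1\], same shape as the input.
#' @export
sliding_window_predict <- function(net, volume, patch_size = c(64L, 64L, 32L),
                                   overlap = 0.5) {
  patch_size <- as.integer(patch_size)
  if (any(patch_size %% 8L != 0L))
    stop("patch dims must be divisible by 8")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  pd <- pad_to(volume, patch_size)
  v <- pd$arr
  d <- dim(v)
  stride <- pmax(1L, as.integer(round(patch_size * (1 - overlap))))
  acc <- array(0, dim = d)
  wt <- array(0, dim = d)
  for (sx in tile_starts(d[1], patch_size[1], stride[1]))
    for (sy in tile_starts(d[2], patch_size[2], stride[2]))
      for (sz in tile_starts(d[3], patch_size[3], stride[3])) {
        ix <- sx + seq_len(patch_size[1])
        iy <- sy + seq_len(patch_size[2])
        iz <- sz + seq_len(patch_size[3])
        z <- network_forward(net, v[ix, iy, iz, drop = FALSE],
                             training = FALSE)
        acc[ix, iy, iz] <- acc[ix, iy, iz] + sigmoid(z[, , , 1])
        wt[ix, iy, iz] <- wt[ix, iy, iz] + 1
      }
  prob <- acc / wt
  lo <- pd$lo
  prob[lo[1] + seq_len(pd$orig[1]), lo[2] + seq_len(pd$orig[2]),
       lo[3] + seq_len(pd$orig[3]), drop = FALSE]
}

#' Two-stage liver and tumor prediction
#'
#' Full cascade on a raw HU volume: preprocessing, stage-1 liver
#' segmentation (threshold 0.5, largest component), ROI extraction with
#' margin, stage-2 tumor segmentation restricted to the ROI, clamping of
#' the tumor mask to the liver, restoration to the original grid and
#' composition of the \{0, 1, 2\} label map.
#'
#' @param liver_net,tumor_net trained networks.
#' @param raw a [ct_volume()] in HU.
#' @param threshold probability threshold for both stages.
#' @param roi_margin ROI margin in voxels.
#' @param patch_size sliding-window patch.
#' @param overlap sliding-window overlap.
#' @return list of class \code{cascade_result}: \code{liver} and
#'   \code{tumor} ([ct_mask()] in original space, tumor contained in
#'   liver), \code{label_map} (\{0, 1, 2\} array), \code{record} (the
#'   [preprocess_record()]) and \code{empty_liver} flag.
#' @export
two_stage_predict <- function(liver_net, tumor_net, raw, threshold = 0.5,
                              roi_margin = 10L,
                              patch_size = c(64L, 64L, 32L), overlap = 0.5) {
  stopifnot(inherits(raw, "ct_volume"))
  pp <- preprocess_case(raw)
  x <- pp$volume$voxels
  liver_prob <- sliding_window_predict(liver_net, x, patch_size, overlap)
  liver <- largest_component(liver_prob >= threshold)
  d <- dim(x)
  tumor <- array(FALSE, dim = d)
  empty_liver <- !any(liver)
  if (!empty_liver) {
    roi <- liver_roi(liver, roi_margin)
    ix <- (roi$lo[1] + 1L):roi$hi[1]
    iy <- (roi$lo[2] + 1L):roi$hi[2]
    iz <- (roi$lo[3] + 1L):roi$hi[3]
    tprob <- sliding_window_predict(tumor_net,
                                    x[ix, iy, iz, drop = FALSE],
                                    patch_size, overlap)
    tumor[ix, iy, iz] <- tprob >= threshold
    tumor <- tumor & liver              # containment clamp
  }
  sp <- pp$volume$spacing
  liver_orig <- restore_to_original(ct_mask(liver, sp), pp$record)
  tumor_orig <- restore_to_original(ct_mask(tumor, sp), pp$record)
  tumor_orig$voxels <- tumor_orig$voxels & liver_orig$voxels
  label <- array(0L, dim = pp$record$original_shape)
  label[liver_orig$voxels] <- 1L
  label[tumor_orig$voxels] <- 2L
  structure(list(liver = liver_orig, tumor = tumor_orig, label_map = label,
                 record = pp$record, empty_liver = empty_liver),
            class = "cascade_result")
}
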