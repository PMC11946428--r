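# NIfTI ingestion and export following the LiTS naming convention
# (volume-{i}.nii.gz / segmentation-{i}.nii.gz, labels 0/1/2).

#' Read a CT case from NIfTI
#'
#' @param volume_path path to the intensity volume (.nii or .nii.gz).
#' @param label_path optional path to the label volume (values 0, 1, 2).
#' @return list with \code{volume} (a [ct_volume()] in HU) and, when
#'   requested, \code{label} (3D integer array).
#' @export
read_case <- function(volume_path, label_path = NULL) {
  if (!file.exists(volume_path)) stop("no such file: ", volume_path)
  img <- RNifti::readNifti(volume_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), "D: ", volume_path)
  sp <- RNifti::pixdim(img)[1:3]
  out <- list(volume = ct_volume(arr, sp, "HU"))
  if (!is.null(label_path)) {
    if (!file.exists(label_path)) stop("no such file: ", label_path)
    lim <- RNifti::readNifti(label_path)
    lab <- as.array(lim)
    if (length(dim(lab)) != 3L)
      stop("expected a 3D label image: ", label_path)
    if (!identical(dim(lab), dim(arr)))
      stop("label and volume grids differ")
    bad <- setdiff(unique(as.vector(lab)), c(0, 1, 2))
    if (length(bad))
      stop("unexpected label values (", paste(bad, collapse = ", "),
           "); expected {0, 1, 2}")
    out$label <- array(as.integer(lab), dim = dim(lab))
  }
  out
}

write_nifti_array <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr, datatype = "auto")
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a label map (or mask) restored to original space
#'
#' When a [preprocess_record()] is given, the mask is first restored to the
#' original grid with [restore_to_original()].
#'
#' @param mask a [ct_mask()] or an integer label array wrapped in a mask.
#' @param path destination (.nii or .nii.gz).
#' @param record optional [preprocess_record()].
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path, record = NULL) {
  if (!is.null(record)) mask <- restore_to_original(mask, record)
  sp <- if (!is.null(record)) record$original_spacing else mask$spacing
  write_nifti_array(array(as.integer(mask$voxels), dim = dim(mask$voxels)),
                    sp, path)
}

#' Write a full {0,1,2} label map
#'
#' @param label 3D integer array with values 0 (background), 1 (liver),
#'   2 (tumor).
#' @param spacing mm spacing triple.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_label_map <- function(label, spacing, path) {
  bad <- setdiff(unique(as.vector(label)), c(0, 1, 2))
  if (length(bad)) stop("label map may only contain {0, 1, 2}")
  write_nifti_array(array(as.integer(label), dim = dim(label)), spacing, path)
}

#' LiTS-style file names
#'
#' @param dir directory.
#' @param i case index.
#' @return named character vector with \code{volume} and \code{segmentation}
#'   paths.
#' @export
lits_paths <- function(dir, i) {
  c(volume = file.path(dir, sprintf("volume-%d.nii.gz", i)),
    segmentation = file.path(dir, sprintf("segmentation-%d.nii.gz", i)))
}
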