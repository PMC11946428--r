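# Evaluation suite: overlap (Dice, precision, recall), volume (RVD),
# surface distance (ASD via an exact anisotropic Euclidean distance
# transform) and per-lesion size measurements (Feret diameters), plus the
# Dice-stratified lesion-size summary.

as_mask_array <- function(m) {
  if (inherits(m, "ct_mask")) m$voxels else m != 0
}

check_same_shape <- function(A, B) {
  if (!identical(dim(A), dim(B)))
    stop("mask shapes differ: ", paste(dim(A), collapse = "x"), " vs ",
         paste(dim(B), collapse = "x"))
  invisible(NULL)
}

#' Dice overlap score
#'
#' \code{2|A n B| / (|A| + |B|)}; defined as 1 when both masks are empty.
#'
#' @param A,B binary 3D arrays or [ct_mask()] objects of equal shape
#'   (prediction and ground truth; the score is symmetric).
#' @return scalar in \[0, 1\].
#' @export
dice_score <- function(A, B) {
  A <- as_mask_array(A); B <- as_mask_array(B)
  check_same_shape(A, B)
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0) return(1)
  2 * sum(A & B) / (sa + sb)
}

#' Extract the boundary voxels of a mask
#'
#' A mask voxel is boundary if at least one of its 6 face neighbors is
#' outside the mask; the grid border counts as outside.
#'
#' @param mask binary 3D array or [ct_mask()]; must be nonempty.
#' @param spacing mm spacing (taken from the mask when available).
#' @return list with \code{voxels} (logical array marking surface voxels)
#'   and \code{points} (n x 3 matrix of surface voxel centers in mm).
#' @export
extract_surface <- function(mask, spacing = NULL) {
  if (inherits(mask, "ct_mask") && is.null(spacing)) spacing <- mask$spacing
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  m <- as_mask_array(mask)
  if (!any(m)) stop("surface of an empty mask is undefined")
  d <- dim(m)
  interior <- array(TRUE, dim = d)
  shift_ok <- function(ax, dir) {
    s <- array(FALSE, dim = d)
    n <- d[ax]
    if (n == 1L) return(s)             # everything borders the outside
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (dir > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    do.call(`[<-`, c(list(s), idx_dst,
                     list(do.call(`[`, c(list(m), idx_src)))))
  }
  for (ax in 1:3) for (dir in c(-1, 1))
    interior <- interior & shift_ok(ax, dir)
  surf <- m & !interior
  idx <- which(surf, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, spacing, "*")
  colnames(pts) <- c("x", "y", "z")
  list(voxels = surf, points = pts)
}

#' Average symmetric surface distance (mm)
#'
#' Mean Euclidean distance (in mm, voxel centers, anisotropic spacing)
#' between the boundary point sets of the two masks, averaged over both
#' directions: \code{[sum d(a, S(B)) + sum d(b, S(A))] / (|S(A)| + |S(B)|)}.
#' Distances are computed with an exact anisotropic Euclidean distance
#' transform, which matches the all-pairs definition exactly.
#'
#' @param A,B nonempty binary 3D arrays or [ct_mask()] of equal shape.
#' @param spacing mm spacing triple.
#' @return scalar distance in mm.
#' @export
asd <- function(A, B, spacing = c(1, 1, 1)) {
  if (inherits(A, "ct_mask")) spacing <- A$spacing
  Am <- as_mask_array(A); Bm <- as_mask_array(B)
  check_same_shape(Am, Bm)
  if (!any(Am) || !any(Bm))
    stop("ASD is undefined for empty masks")
  sA <- extract_surface(Am, spacing)$voxels
  sB <- extract_surface(Bm, spacing)$voxels
  dB <- .cpp_distance_to_sites(sB, as.numeric(spacing))
  dA <- .cpp_distance_to_sites(sA, as.numeric(spacing))
  (sum(dB[sA]) + sum(dA[sB])) / (sum(sA) + sum(sB))
}

#' Relative volume difference
#'
#' \code{(|B| - |A|) / |A|} with A the prediction and B the ground truth.
#'
#' @param A,B binary 3D arrays or [ct_mask()]; \code{|A|} must be positive.
#' @return signed scalar.
#' @export
rvd <- function(A, B) {
  A <- as_mask_array(A); B <- as_mask_array(B)
  check_same_shape(A, B)
  sa <- sum(A)
  if (sa == 0) stop("RVD is undefined for an empty prediction")
  (sum(B) - sa) / sa
}

#' Voxel precision and recall
#'
#' \code{TP/(TP+FP)} and \code{TP/(TP+FN)} with A the prediction, B the
#' ground truth; 0 when the respective denominator is 0.
#'
#' @param A,B binary 3D arrays or [ct_mask()] of equal shape.
#' @return named numeric vector \code{c(precision, recall)}.
#' @export
precision_recall <- function(A, B) {
  A <- as_mask_array(A); B <- as_mask_array(B)
  check_same_shape(A, B)
  tp <- sum(A & B)
  fp <- sum(A & !B)
  fn <- sum(!A & B)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

#' Per-lesion major-axis lengths (Feret diameters, mm)
#'
#' Labels 26-connected components and returns, for each, the maximum
#' pairwise Euclidean distance between its surface voxel centers in mm.
#'
#' @param mask binary 3D array or [ct_mask()].
#' @param spacing mm spacing triple.
#' @return numeric vector, one length per lesion (empty for empty masks).
#' @export
major_axis_length <- function(mask, spacing = c(1, 1, 1)) {
  if (inherits(mask, "ct_mask")) spacing <- mask$spacing
  m <- as_mask_array(mask)
  if (!any(m)) return(numeric(0))
  lab <- .cpp_label_components(m, 26L)
  ncomp <- max(lab)
  out <- numeric(ncomp)
  for (k in seq_len(ncomp)) {
    comp <- lab == k
    dim(comp) <- dim(m)
    pts <- extract_surface(comp, spacing)$points
    out[k] <- .cpp_max_pairwise_dist(pts)
  }
  out
}

#' Stratify cases by Dice score and summarize lesion sizes
#'
#' Partitions cases into a high-performance group (Dice >= threshold) and a
#' low-performance group (Dice < threshold) and reports the mean lesion
#' major-axis length per group.
#'
#' @param cases data.frame with a \code{dice} column and a list-column (or
#'   semicolon-separated character column) \code{lengths_mm} of per-lesion
#'   major-axis lengths.
#' @param threshold Dice boundary; boundary cases fall in the high group.
#' @return data.frame with one row per group: group, number of cases,
#'   number of lesions and mean major-axis length (NA for empty groups).
#' @export
stratify_cases <- function(cases, threshold = 0.6) {
  if (NROW(cases) == 0)
    return(data.frame(group = character(), n_cases = integer(),
                      n_lesions = integer(), mean_major_axis_mm = numeric()))
  get_lengths <- function(v) {
    if (is.list(v)) return(unlist(v))
    parts <- unlist(strsplit(as.character(v), ";"))
    as.numeric(parts[nzchar(parts)])
  }
  hi <- cases$dice >= threshold
  summarize <- function(sel, name) {
    lens <- get_lengths(cases$lengths_mm[sel])
    data.frame(group = name, n_cases = sum(sel), n_lesions = length(lens),
               mean_major_axis_mm = if (length(lens)) mean(lens) else NA_real_)
  }
  rbind(summarize(hi, "high"), summarize(!hi, "low"))
}

#' Evaluate one predicted case against ground truth
#'
#' Liver metrics: Dice and ASD. Tumor metrics: Dice, ASD, RVD, precision
#' and recall, plus per-lesion major-axis lengths of the ground-truth
#' lesions. ASD is reported in mm and in (mean-spacing) voxel units; it is
#' NA when either surface is empty, and tumor-absent cases are flagged.
#'
#' @param pred_label,true_label 3D integer arrays with labels \{0, 1, 2\}.
#' @param spacing mm spacing triple.
#' @return one-row data.frame of the per-case metrics.
#' @export
evaluate_case <- function(pred_label, true_label, spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(pred_label), dim(true_label)))
  liv_p <- pred_label >= 1L; liv_t <- true_label >= 1L
  tum_p <- pred_label == 2L; tum_t <- true_label == 2L
  safe_asd <- function(A, B) {
    if (!any(A) || !any(B)) return(NA_real_)
    asd(A, B, spacing)
  }
  pr <- precision_recall(tum_p, tum_t)
  vox <- mean(spacing)                # voxel-unit ASD alongside mm
  liver_asd <- safe_asd(liv_p, liv_t)
  tumor_asd <- safe_asd(tum_p, tum_t)
  data.frame(
    liver_dice = dice_score(liv_p, liv_t),
    liver_asd_mm = liver_asd,
    liver_asd_vox = liver_asd / vox,
    tumor_present = any(tum_t),
    tumor_detected = any(tum_p),
    tumor_dice = dice_score(tum_p, tum_t),
    tumor_asd_mm = tumor_asd,
    tumor_asd_vox = tumor_asd / vox,
    tumor_rvd = if (any(tum_p)) rvd(tum_p, tum_t) else NA_real_,
    tumor_precision = pr[["precision"]],
    tumor_recall = pr[["recall"]],
    lengths_mm = paste(sprintf("%.3f", major_axis_length(tum_t, spacing)),
                       collapse = ";"))
}
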