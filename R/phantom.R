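# Synthetic abdominal CT phantoms: a body ellipsoid in air, a liver-like
# ellipsoid inside it and spherical tumors inside the liver, rasterized on
# an anisotropic grid with Gaussian HU noise. Ground-truth labels are exact
# by construction, so segmentation metrics computed on phantoms have
# analytic oracles (ellipsoid volumes, sphere diameters).

#' Phantom specification
#'
#' Geometry is expressed in mm relative to the grid center; defaults mimic
#' a portal-venous abdominal CT at desk scale: liver parenchyma around
#' 60 HU, hypodense lesions around 30 HU, both inside the -200..200 HU
#' preprocessing window, with mild noise so a small network can learn the
#' contrast quickly.
#'
#' @param shape grid dims (x, y, z).
#' @param spacing mm per voxel; anisotropic by default.
#' @param body_semiaxes,body_center body ellipsoid (mm).
#' @param liver_semiaxes,liver_center liver ellipsoid (mm).
#' @param n_tumors number of spherical tumors.
#' @param tumor_radius_range min/max tumor radius (mm).
#' @param hu_air,hu_body,hu_liver,hu_tumor region mean intensities (HU).
#' @param noise_sd Gaussian HU noise standard deviation.
#' @param boundary_tumors allow tumors to touch the liver boundary (the
#'   sphere is clipped to the liver); exercises the containment clamp.
#' @param seed RNG seed; identical spec and seed give bit-identical output.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 32L),
                         spacing = c(1.5, 1.5, 2.5),
                         body_semiaxes = c(88, 80, 100),
                         body_center = c(0, 0, 0),
                         liver_semiaxes = c(34, 27, 24),
                         liver_center = c(-15, -8, 0),
                         n_tumors = 2L,
                         tumor_radius_range = c(5, 11),
                         hu_air = -1000, hu_body = 0, hu_liver = 60,
                         hu_tumor = 30, noise_sd = 10,
                         boundary_tumors = FALSE, seed = 1L) {
  chk <- (abs(liver_center - body_center) + liver_semiaxes) / body_semiaxes
  if (sum(chk^2) > 3 && any(chk > 1))
    stop("liver ellipsoid is not contained in the body ellipsoid")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 body_semiaxes = body_semiaxes, body_center = body_center,
                 liver_semiaxes = liver_semiaxes, liver_center = liver_center,
                 n_tumors = as.integer(n_tumors),
                 tumor_radius_range = tumor_radius_range,
                 hu_air = hu_air, hu_body = hu_body, hu_liver = hu_liver,
                 hu_tumor = hu_tumor, noise_sd = noise_sd,
                 boundary_tumors = isTRUE(boundary_tumors),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

axis_coords <- function(n, sp) (seq_len(n) - (n + 1) / 2) * sp

ellipsoid_mask <- function(shape, spacing, center, semiaxes) {
  cx <- (axis_coords(shape[1], spacing[1]) - center[1]) / semiaxes[1]
  cy <- (axis_coords(shape[2], spacing[2]) - center[2]) / semiaxes[2]
  cz <- (axis_coords(shape[3], spacing[3]) - center[3]) / semiaxes[3]
  q <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  q <= 1
}

place_tumors <- function(spec, max_tries = 200L) {
  ls <- spec$liver_semiaxes
  lc <- spec$liver_center
  tumors <- list()
  for (t in seq_len(spec$n_tumors)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, spec$tumor_radius_range[1],
                        spec$tumor_radius_range[2])
      # sample the center inside the radius-shrunk liver ellipsoid so the
      # sphere fits; in boundary mode inside the full ellipsoid instead
      shrink <- if (spec$boundary_tumors) ls else ls - r
      if (any(shrink <= 0)) next
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) > 1) next
      ctr <- lc + u * shrink
      ok <- TRUE
      for (prev in tumors) {
        if (sqrt(sum((ctr - prev$center)^2)) <= r + prev$radius + 1) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      tumors[[length(tumors) + 1L]] <- list(center = ctr, radius = r)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place tumor ", t, " inside the liver after ",
           max_tries, " tries; use smaller tumor radii")
  }
  tumors
}

#' Generate one phantom case
#'
#' @param spec a [phantom_spec()].
#' @return list with \code{volume} (a [ct_volume()] in HU), \code{label}
#'   (3D integer array, 0 background / 1 liver / 2 tumor) and \code{truth}
#'   (analytic geometry: liver volume in mm^3, tumor centers, radii and
#'   diameters).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  shape <- spec$shape
  sp <- spec$spacing
  body <- ellipsoid_mask(shape, sp, spec$body_center, spec$body_semiaxes)
  liver <- ellipsoid_mask(shape, sp, spec$liver_center, spec$liver_semiaxes)
  liver <- liver & body
  tumors <- place_tumors(spec)
  tumor <- array(FALSE, dim = shape)
  for (tm in tumors) {
    s <- ellipsoid_mask(shape, sp, tm$center, rep(tm$radius, 3))
    tumor <- tumor | s
  }
  tumor <- tumor & liver        # containment clamp (relevant in boundary mode)
  hu <- array(spec$hu_air, dim = shape)
  hu[body] <- spec$hu_body
  hu[liver] <- spec$hu_liver
  hu[tumor] <- spec$hu_tumor
  if (spec$noise_sd > 0)
    hu <- hu + array(stats::rnorm(prod(shape), sd = spec$noise_sd),
                     dim = shape)
  label <- array(0L, dim = shape)
  label[liver] <- 1L
  label[tumor] <- 2L
  list(volume = ct_volume(hu, sp, "HU"),
       label = label,
       truth = list(
         liver_volume_mm3 = 4 / 3 * pi * prod(spec$liver_semiaxes),
         body_mask = body, liver_mask = liver, tumor_mask = tumor,
         tumor_centers = lapply(tumors, `[[`, "center"),
         tumor_radii = vapply(tumors, `[[`, 0, "radius"),
         tumor_diameters_mm = 2 * vapply(tumors, `[[`, 0, "radius")))
}

#' Generate a LiTS-style phantom dataset
#'
#' Writes \code{n_cases} NIfTI pairs (\code{volume-i.nii.gz},
#' \code{segmentation-i.nii.gz}) with per-case randomized liver geometry and
#' tumor load, plus a \code{manifest.csv} of the analytic ground truth.
#'
#' @param n_cases number of cases.
#' @param out_dir output directory (created if missing).
#' @param seed base seed; case i uses \code{seed * 1000 + i}.
#' @param boundary_tumors passed through to [phantom_spec()].
#' @param shape,spacing grid geometry shared by all cases.
#' @return the manifest as a data.frame (invisibly), written to
#'   \code{out_dir/manifest.csv}.
#' @export
generate_dataset <- function(n_cases, out_dir, seed = 17L,
                             boundary_tumors = FALSE,
                             shape = c(128L, 128L, 32L),
                             spacing = c(1.5, 1.5, 2.5)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    spec <- case_spec(seed, i, boundary_tumors, shape, spacing)
    ph <- generate_phantom(spec)
    paths <- lits_paths(out_dir, i)
    write_nifti_array(ph$volume$voxels, spacing, paths[["volume"]])
    write_label_map(ph$label, spacing, paths[["segmentation"]])
    rows[[i]] <- data.frame(
      case = i,
      liver_volume_mm3 = ph$truth$liver_volume_mm3,
      liver_voxels = sum(ph$label >= 1L),
      n_tumors = length(ph$truth$tumor_radii),
      tumor_diameters_mm = paste(sprintf("%.3f", ph$truth$tumor_diameters_mm),
                                 collapse = ";"))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# per-case randomized specification, deterministic in (seed, i)
case_spec <- function(seed, i, boundary_tumors = FALSE,
                      shape = c(128L, 128L, 32L), spacing = c(1.5, 1.5, 2.5)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed * 1000L + i)
  phantom_spec(shape = shape, spacing = spacing,
               liver_semiaxes = c(stats::runif(1, 30, 38),
                                  stats::runif(1, 24, 30),
                                  stats::runif(1, 20, 26)),
               liver_center = c(stats::runif(1, -18, -10),
                                stats::runif(1, -12, -4),
                                stats::runif(1, -4, 4)),
               n_tumors = sample(1:3, 1),
               boundary_tumors = boundary_tumors,
               seed = seed * 1000L + i + 500L)
}
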