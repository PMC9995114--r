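## 3D component counting, volume/density statistics and distance-based
## membrane-contact-site quantification on label masks. Distances are
## physical (nm), computed with an exact anisotropic Euclidean distance
## transform over voxel dims (step_nm, pixel_nm, pixel_nm).

#' Label connected components (26-connectivity in 3D, 8 in 2D)
#'
#' @param mask logical/binary array, 2D (y, x) or 3D (z, y, x).
#' @return integer array of the same shape; 0 = background, k = component.
#' @export
label_components <- function(mask) {
  two_d <- is.matrix(mask)
  if (two_d) mask <- array(mask, c(1L, dim(mask)))
  stopifnot(length(dim(mask)) == 3L)
  lab <- .cc_label_3d(as.logical(mask > 0), as.integer(dim(mask)))
  if (two_d) lab <- lab[1L, , ]
  lab
}

#' Anisotropic Euclidean distance map to a mask (nm)
#'
#' Exact distance from every voxel to the nearest mask voxel, measured in
#' nm with voxel dimensions `(step_nm, pixel_nm, pixel_nm)` along
#' `(z, y, x)`. Mask voxels have distance 0.
#'
#' @param mask logical/binary 3D array (a 2D matrix is treated as one
#'   slice).
#' @param pixel_nm lateral pixel size (nm).
#' @param step_nm slice step (nm); defaults to `pixel_nm` for 2D input.
#' @return numeric array of distances in nm (Inf if the mask is empty).
#' @export
distance_to_mask_nm <- function(mask, pixel_nm, step_nm = pixel_nm) {
  two_d <- is.matrix(mask)
  if (two_d) mask <- array(mask, c(1L, dim(mask)))
  d2 <- .edt_sq_3d(as.logical(mask > 0), as.integer(dim(mask)),
                   as.numeric(c(step_nm, pixel_nm, pixel_nm)))
  d <- sqrt(d2)
  if (two_d) d <- d[1L, , ]
  d
}

.voxel_um3 <- function(pixel_nm, step_nm) pixel_nm^2 * step_nm * 1e-9

#' 3D connected-component report
#'
#' Labels the mask with 26-connectivity, drops components smaller than
#' `min_voxels`, and reports per-component voxel counts, volumes in cubic
#' micrometres (`count * pixel_nm^2 * step_nm * 1e-9`) and centroids, plus
#' the component density over the analysed volume.
#'
#' @param mask binary 3D array (z, y, x).
#' @param pixel_nm,step_nm voxel dimensions (nm).
#' @param min_voxels components with fewer voxels are removed (the
#'   small-segmentation filter; 0 keeps everything).
#' @return object of class `component_report`: data frame `components`
#'   (`id`, `voxels`, `volume_um3`, `centroid_z/y/x`), `n_components`,
#'   `total_volume_um3`, `analysed_volume_um3`, `density_per_um3`,
#'   `min_voxels`.
#' @export
components3d <- function(mask, pixel_nm, step_nm, min_voxels = 0L) {
  if (is.matrix(mask)) mask <- array(mask, c(1L, dim(mask)))
  lab <- label_components(mask)
  vox_um3 <- .voxel_um3(pixel_nm, step_nm)
  counts <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(counts >= min_voxels)
  comp <- if (length(keep)) {
    idx <- which(lab > 0L)
    ids <- lab[idx]
    coords <- arrayInd(idx, dim(lab))
    in_keep <- ids %in% keep
    ids2 <- ids[in_keep]; coords <- coords[in_keep, , drop = FALSE]
    data.frame(
      id = seq_along(keep),
      voxels = counts[keep],
      volume_um3 = counts[keep] * vox_um3,
      centroid_z = tapply(coords[, 1], ids2, mean)[as.character(keep)],
      centroid_y = tapply(coords[, 2], ids2, mean)[as.character(keep)],
      centroid_x = tapply(coords[, 3], ids2, mean)[as.character(keep)],
      row.names = NULL)
  } else {
    data.frame(id = integer(), voxels = integer(), volume_um3 = numeric(),
               centroid_z = numeric(), centroid_y = numeric(),
               centroid_x = numeric())
  }
  analysed <- length(lab) * vox_um3
  structure(list(components = comp, n_components = nrow(comp),
                 total_volume_um3 = sum(comp$volume_um3),
                 analysed_volume_um3 = analysed,
                 density_per_um3 = nrow(comp) / analysed,
                 min_voxels = as.integer(min_voxels)),
            class = "component_report")
}

#' @export
print.component_report <- function(x, ...) {
  cat(sprintf(
    "component_report: %d components (min %d voxels), total %.4g um^3, density %.3g per um^3\n",
    x$n_components, x$min_voxels, x$total_volume_um3, x$density_per_um3))
  invisible(x)
}

#' Membrane contact sites between two organelle masks
#'
#' The contact region consists of the voxels lying within `gap_nm` of both
#' masks (anisotropic Euclidean distance in nm) but inside neither, plus
#' any voxels where the masks overlap. Its 26-connected components are the
#' individual contact sites.
#'
#' @param maskA,maskB binary 3D arrays of identical shape.
#' @param pixel_nm,step_nm voxel dimensions (nm).
#' @param gap_nm maximum membrane separation counted as contact
#'   (default 25).
#' @return object of class `contact_report`: data frame `sites` (`id`,
#'   `voxels`, `volume_um3`), `n_sites`, `total_volume_um3`, `gap_nm` and
#'   the binary `region`.
#' @export
contact_sites <- function(maskA, maskB, pixel_nm, step_nm, gap_nm = 25) {
  if (is.matrix(maskA)) maskA <- array(maskA, c(1L, dim(maskA)))
  if (is.matrix(maskB)) maskB <- array(maskB, c(1L, dim(maskB)))
  if (!identical(dim(maskA), dim(maskB))) stop("shape mismatch")
  if (gap_nm < 0) stop("gap_nm must be >= 0")
  A <- maskA > 0; B <- maskB > 0
  dA <- distance_to_mask_nm(A, pixel_nm, step_nm)
  dB <- distance_to_mask_nm(B, pixel_nm, step_nm)
  region <- (dA <= gap_nm & dB <= gap_nm & !A & !B) | (A & B)
  lab <- label_components(region)
  counts <- tabulate(lab[lab > 0L], nbins = max(lab))
  vox_um3 <- .voxel_um3(pixel_nm, step_nm)
  sites <- data.frame(id = seq_along(counts), voxels = counts,
                      volume_um3 = counts * vox_um3)
  structure(list(sites = sites, n_sites = nrow(sites),
                 total_volume_um3 = sum(sites$volume_um3),
                 gap_nm = gap_nm, region = region),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf(
    "contact_report: %d site(s) at gap <= %g nm, total volume %.4g um^3\n",
    x$n_sites, x$gap_nm, x$total_volume_um3))
  invisible(x)
}

#' Volumes and volume fractions of a set of masks
#'
#' @param masks named list of binary 3D arrays of identical shape.
#' @param pixel_nm,step_nm voxel dimensions (nm).
#' @param fov optional binary mask of the analysed field of view; default
#'   the full grid.
#' @return data frame with columns `name`, `voxels`, `volume_um3`,
#'   `fraction` (of FOV volume); the FOV itself is the first row.
#' @export
volume_fractions <- function(masks, pixel_nm, step_nm, fov = NULL) {
  stopifnot(is.list(masks), length(masks) > 0, !is.null(names(masks)))
  dims <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), dims)) stop("shape mismatch")
  if (is.null(fov)) fov <- array(TRUE, dims)
  if (!identical(dim(fov), dims)) stop("fov shape mismatch")
  vox_um3 <- .voxel_um3(pixel_nm, step_nm)
  fov_vox <- sum(fov > 0)
  rows <- data.frame(name = "fov", voxels = fov_vox,
                     volume_um3 = fov_vox * vox_um3, fraction = 1.0)
  for (nm in names(masks)) {
    v <- sum(masks[[nm]] > 0)
    rows <- rbind(rows, data.frame(name = nm, voxels = v,
                                   volume_um3 = v * vox_um3,
                                   fraction = v / fov_vox))
  }
  rows
}
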