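#' Clip a CT mask to the aOCT field of view
#'
#' The aOCT acquisition misses airway beyond its pullback span and
#' imaging range, so the reference CT mask is clipped in the posterior
#' direction (beyond the aOCT mask's last occupied slice along axis 3)
#' and in the cranial and caudal directions (beyond its occupied extent
#' along axis 2). The anterior, medial and lateral directions are left
#' untouched.
#'
#' @param ct_mask,aoct_mask binary [voxel_grid]s on the same
#'   airflow-aligned geometry (the aOCT mask already registered).
#' @return list with `mask` (clipped CT) and `clip_extents_mm`
#'   (named: posterior, cranial, caudal plane positions in mm).
#' @export
clip_to_fov <- function(ct_mask, aoct_mask) {
  stopifnot(inherits(ct_mask, "voxel_grid"), ct_mask$binary,
            inherits(aoct_mask, "voxel_grid"), aoct_mask$binary)
  if (!same_geometry(ct_mask, aoct_mask))
    stop("masks are not on the same grid geometry")
  if (!any(aoct_mask$data == 1L)) stop("aOCT mask is empty")
  occ <- which(aoct_mask$data == 1L, arr.ind = TRUE)
  kmax <- max(occ[, 3])     # posterior-most occupied slice
  jmax <- max(occ[, 2])     # cranial
  jmin <- min(occ[, 2])     # caudal
  data <- ct_mask$data
  d <- dim(data)
  if (kmax < d[3]) data[, , (kmax + 1L):d[3]] <- 0L
  if (jmax < d[2]) data[, (jmax + 1L):d[2], ] <- 0L
  if (jmin > 1L) data[, 1:(jmin - 1L), ] <- 0L
  zc <- axis_coords(ct_mask, 3); yc <- axis_coords(ct_mask, 2)
  list(mask = voxel_grid(data, ct_mask$spacing_mm, ct_mask$origin_mm,
                         binary = TRUE),
       clip_extents_mm = c(posterior = zc[kmax], cranial = yc[jmax],
                           caudal = yc[jmin]))
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b binary [voxel_grid]s on the same geometry.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "voxel_grid"), a$binary,
            inherits(b, "voxel_grid"), b$binary)
  if (!same_geometry(a, b)) stop("masks are not on the same grid geometry")
  na <- sum(a$data == 1L); nb <- sum(b$data == 1L)
  if (na + nb == 0L) return(1)
  2 * sum(a$data == 1L & b$data == 1L) / (na + nb)
}

#' Symmetric Hausdorff distance between two surfaces
#'
#' For binary grids the surfaces are their boundary voxel centers
#' ([boundary_points]); meshes and raw matrices contribute their
#' vertices. The full maximum (not a percentile) of the two directed
#' nearest-neighbour distances is returned, together with the per-point
#' distances for colormap rendering.
#'
#' @param a,b binary [voxel_grid]s, [surface_mesh]es or n x 3 point
#'   matrices.
#' @return list with `hd_mm`, `a_to_b` and `b_to_a` per-point distance
#'   vectors.
#' @export
hausdorff <- function(a, b) {
  as_pts <- function(x) {
    if (inherits(x, "voxel_grid")) boundary_points(x) else mesh_points(x)
  }
  pa <- as_pts(a); pb <- as_pts(b)
  if (nrow(pa) == 0 || nrow(pb) == 0) stop("empty surface")
  dab <- nn_lookup_cpp(pa, pb)$dist
  dba <- nn_lookup_cpp(pb, pa)$dist
  list(hd_mm = max(max(dab), max(dba)), a_to_b = dab, b_to_a = dba)
}

#' Full CT versus aOCT comparison
#'
#' Applies the rigid transform to the aOCT mask, resamples it onto the CT
#' grid, clips the CT mask to the aOCT field of view, and computes the
#' study's comparison metrics: volumes, volume difference (CT - aOCT,
#' also as percent of CT), Dice similarity coefficient and symmetric
#' Hausdorff distance on the clipped pair.
#'
#' @param ct_mask binary [voxel_grid] (reference, airflow-aligned).
#' @param aoct_mask binary [voxel_grid] (reconstructed lumen).
#' @param transform [rigid_transform] mapping aOCT to CT coordinates
#'   (identity if omitted).
#' @return a `comparison_report`: list with `ct_volume_mm3`,
#'   `aoct_volume_mm3`, `volume_diff_mm3`, `volume_diff_pct`, `dsc`,
#'   `hd_mm`, `clip_extents_mm` and `per_point_distances_mm`.
#' @export
compare_masks <- function(ct_mask, aoct_mask, transform = rigid_transform()) {
  stopifnot(inherits(ct_mask, "voxel_grid"), ct_mask$binary)
  aoct_on_ct <- if (same_geometry(ct_mask, aoct_mask) &&
                    max(abs(transform$rotation - diag(3))) < 1e-12 &&
                    max(abs(transform$translation_mm)) < 1e-12)
    aoct_mask
  else resample_mask(aoct_mask, transform, ct_mask)
  clip <- clip_to_fov(ct_mask, aoct_on_ct)
  ctv <- volume_mm3(clip$mask)
  aov <- volume_mm3(aoct_on_ct)
  hd <- if (ctv == 0 || aov == 0) list(hd_mm = NA_real_, a_to_b = numeric(0))
  else hausdorff(clip$mask, aoct_on_ct)
  structure(list(
    ct_volume_mm3 = ctv,
    aoct_volume_mm3 = aov,
    volume_diff_mm3 = ctv - aov,
    volume_diff_pct = if (ctv > 0) 100 * (ctv - aov) / ctv else NA_real_,
    dsc = dice(clip$mask, aoct_on_ct),
    hd_mm = hd$hd_mm,
    clip_extents_mm = clip$clip_extents_mm,
    per_point_distances_mm = hd$a_to_b),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<comparison_report>\n",
    "  CT volume (clipped): %.1f mm^3\n  aOCT volume: %.1f mm^3\n",
    "  difference: %.1f mm^3 (%.1f%% of CT)\n",
    "  DSC: %.3f\n  Hausdorff distance: %.3f mm\n"),
    x$ct_volume_mm3, x$aoct_volume_mm3, x$volume_diff_mm3,
    x$volume_diff_pct, x$dsc, x$hd_mm))
  invisible(x)
}
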