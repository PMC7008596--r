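#' Airflow axis from two anatomical landmarks
#'
#' The airflow direction is defined by an anterior landmark (naris analog)
#' and a posterior landmark (choana analog); cross-sections are taken
#' perpendicular to it.
#'
#' @param anterior_mm,posterior_mm 3-D landmark coordinates in mm.
#' @return an `airflow_axis`: list with the two points and `unit_vector`.
#' @export
airflow_axis <- function(anterior_mm, posterior_mm) {
  d <- posterior_mm - anterior_mm
  len <- sqrt(sum(d^2))
  if (len < 1e-9) stop("airflow axis degenerate: landmarks coincide")
  structure(list(anterior_point_mm = as.numeric(anterior_mm),
                 posterior_point_mm = as.numeric(posterior_mm),
                 unit_vector = d / len),
            class = "airflow_axis")
}

#' Airflow axis from the principal direction of the air voxels
#'
#' Fallback when no landmarks are available: the first principal component
#' of the air voxel centers, oriented towards increasing grid axis 3.
#'
#' @param mask a binary [voxel_grid].
#' @return an `airflow_axis`.
#' @export
airflow_axis_pca <- function(mask) {
  stopifnot(inherits(mask, "voxel_grid"), mask$binary)
  idx <- which(mask$data == 1L, arr.ind = TRUE)
  if (nrow(idx) < 2) stop("mask too small for a principal axis")
  pts <- index_to_world(mask, idx)
  ctr <- colMeans(pts)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  u <- ev$vectors[, 1]
  if (u[3] < 0) u <- -u
  span <- pts %*% u
  airflow_axis(ctr + u * (min(span) - sum(ctr * u)),
               ctr + u * (max(span) - sum(ctr * u)))
}

#' Resample a volume perpendicular to the airflow direction
#'
#' Returns an isotropic grid whose third axis is the airflow direction.
#' Binary grids are resampled nearest-neighbour; scalar grids trilinearly.
#' The in-plane basis is chosen so that the cranial-caudal axis stays as
#' close as possible to the input's axis 2.
#'
#' @param grid a [voxel_grid].
#' @param axis an [airflow_axis].
#' @param voxel_mm isotropic output spacing (default 0.33 mm).
#' @return the resampled [voxel_grid] (air/tissue or scalar as input;
#'   scalar voxels falling outside the input take the input minimum).
#' @export
resample_perpendicular <- function(grid, axis, voxel_mm = 0.33) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(axis, "airflow_axis"))
  stopifnot_scalar(voxel_mm, "voxel_mm", positive = TRUE)
  w <- axis$unit_vector
  ref <- if (abs(w[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  u <- c(ref[2] * w[3] - ref[3] * w[2],
         ref[3] * w[1] - ref[1] * w[3],
         ref[1] * w[2] - ref[2] * w[1])
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  basis <- cbind(u, v, w)                    # world <- resampled coords

  d <- dim(grid$data)
  corners <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
  cw <- index_to_world(grid, corners)
  local <- sweep(cw, 2, axis$anterior_point_mm) %*% basis
  lo <- apply(local, 2, min); hi <- apply(local, 2, max)
  n <- pmax(floor((hi - lo) / voxel_mm) + 1L, 1L)

  a <- lo[1] + (seq_len(n[1]) - 1) * voxel_mm
  b <- lo[2] + (seq_len(n[2]) - 1) * voxel_mm
  cc <- lo[3] + (seq_len(n[3]) - 1) * voxel_mm
  abc <- cbind(rep(a, times = n[2] * n[3]),
               rep(rep(b, each = n[1]), times = n[3]),
               rep(cc, each = n[1] * n[2]))
  world <- sweep(abc %*% t(basis), 2, axis$anterior_point_mm, "+")
  vals <- if (grid$binary) {
    s <- sample_nearest(grid, world)
    s[is.na(s)] <- 0
    s
  } else {
    sample_trilinear(grid, world, outside = min(grid$data))
  }
  out <- array(vals, n)
  voxel_grid(out, voxel_mm, origin_mm = lo, binary = grid$binary)
}

#' Threshold-and-grow airway segmentation
#'
#' Thresholds scalar data (air = values below `threshold`) or takes the
#' air label of a binary grid, then keeps the 26-connected component that
#' contains `seed_point_mm`, discarding detached air pockets.
#'
#' @param grid a [voxel_grid].
#' @param threshold scalar threshold (ignored for binary grids).
#' @param seed_point_mm a 3-D point in mm inside the airway.
#' @return a binary [voxel_grid] airway mask.
#' @export
segment_airway <- function(grid, threshold = -500, seed_point_mm) {
  stopifnot(inherits(grid, "voxel_grid"))
  air <- if (grid$binary) grid$data == 1L else grid$data < threshold
  if (!any(air)) stop("threshold yields an empty airway")
  d <- dim(grid$data)
  ij <- round(world_to_index(grid, matrix(seed_point_mm, 1)))
  if (any(ij < 1) || any(ij > d))
    stop("seed point lies outside the grid")
  lin <- (ij[3] - 1) * d[1] * d[2] + (ij[2] - 1) * d[1] + ij[1]
  if (!air[lin]) stop("seed point is not in an air voxel")
  comp <- flood_fill26_cpp(as.logical(air), as.integer(d), as.integer(lin))
  voxel_grid(array(as.integer(comp), d), grid$spacing_mm, grid$origin_mm,
             binary = TRUE)
}

#' Cross-sectional area profile along the airflow axis
#'
#' @param mask a binary [voxel_grid] whose axis 3 is the airflow axis.
#' @return a `csa_profile`: data frame with `position_mm` (slice centers)
#'   and `area_mm2` (air voxel count times in-plane voxel area).
#' @export
csa_profile <- function(mask) {
  stopifnot(inherits(mask, "voxel_grid"), mask$binary)
  nz <- dim(mask$data)[3]
  counts <- colSums(matrix(mask$data, ncol = nz))
  out <- data.frame(position_mm = axis_coords(mask, 3),
                    area_mm2 = counts * prod(mask$spacing_mm[1:2]))
  class(out) <- c("csa_profile", "data.frame")
  out
}

#' Locate the internal nasal valve as the minimum-CSA slice
#'
#' Smooths the profile with a short moving average (to suppress
#' single-voxel noise minima) and returns the argmin of the smoothed
#' areas within the search range; ties are broken towards the most
#' anterior (smallest-position) slice. The reported area is the raw
#' (unsmoothed) area of the selected slice.
#'
#' @param profile a `csa_profile`.
#' @param search_range_mm length-2 interval of positions to search;
#'   default is the anterior third of the profile (the cartilaginous
#'   vault analog).
#' @param smooth_slices moving-average window (slices, odd).
#' @return list with `position_mm` and `area_mm2`.
#' @export
locate_inv <- function(profile, search_range_mm = NULL, smooth_slices = 3L) {
  stopifnot(inherits(profile, "csa_profile"))
  pos <- profile$position_mm
  if (is.null(search_range_mm)) {
    search_range_mm <- c(min(pos), min(pos) + (max(pos) - min(pos)) / 3)
  }
  sel <- pos >= search_range_mm[1] & pos <= search_range_mm[2]
  if (!any(sel)) stop("empty search range")
  h <- (smooth_slices - 1L) %/% 2L
  n <- length(pos)
  smoothed <- vapply(seq_len(n), function(i) {
    w <- max(1L, i - h):min(n, i + h)
    mean(profile$area_mm2[w])
  }, numeric(1))
  cand <- which(sel)
  best <- cand[which.min(smoothed[cand])]   # which.min takes first tie
  list(position_mm = pos[best], area_mm2 = profile$area_mm2[best])
}
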