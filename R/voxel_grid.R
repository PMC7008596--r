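#' Isotropic or anisotropic 3-D voxel grid
#'
#' Container for 3-D scalar or binary volumes with physical spacing.
#' Coordinates are right-handed millimetres; the voxel at array index
#' `[1, 1, 1]` has its *center* at `origin_mm`, and the center of voxel
#' `[i, j, k]` is `origin_mm + (c(i, j, k) - 1) * spacing_mm`.
#' Throughout the package axis 1 runs medial to lateral, axis 2 caudal to
#' cranial and axis 3 anterior to posterior; axis 3 is the airflow /
#' pullback axis. In binary grids air = 1 and tissue = 0.
#'
#' @param data numeric or logical 3-D array.
#' @param spacing_mm per-axis voxel size in mm (length 1 or 3, > 0).
#' @param origin_mm position in mm of the center of voxel `[1, 1, 1]`.
#' @param binary logical; if `TRUE` the data are validated as {0, 1} labels.
#'
#' @return An object of class `voxel_grid`: a list with elements `data`,
#'   `spacing_mm`, `origin_mm`, `binary` and `axis_labels`.
#' @export
voxel_grid <- function(data, spacing_mm, origin_mm = c(0, 0, 0),
                       binary = all(data %in% c(0, 1))) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 strictly positive values")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be 3 finite values")
  storage.mode(data) <- if (binary) "integer" else "double"
  if (binary && !all(data %in% c(0L, 1L)))
    stop("binary grid must contain only 0 and 1")
  structure(
    list(data = data, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm), binary = isTRUE(binary),
         axis_labels = c("medial-lateral", "caudal-cranial",
                         "anterior-posterior")),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 4), collapse = " x "),
              if (x$binary) sprintf("binary (%.1f mm^3 air)", volume_mm3(x))
              else "scalar"))
  invisible(x)
}

#' Physical volume of a binary grid
#'
#' Counts nonzero voxels and multiplies by the voxel volume.
#'
#' @param grid a binary [voxel_grid].
#' @return volume in mm^3.
#' @export
volume_mm3 <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  sum(grid$data != 0) * prod(grid$spacing_mm)
}

# Physical coordinates (mm) of voxel centers along one axis.
axis_coords <- function(grid, axis) {
  grid$origin_mm[axis] +
    (seq_len(dim(grid$data)[axis]) - 1) * grid$spacing_mm[axis]
}

# Continuous (1-based) array index of physical points; pts is n x 3 mm.
world_to_index <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin_mm, "-"), 2, grid$spacing_mm, "/") + 1
}

index_to_world <- function(grid, idx) {
  sweep(sweep(idx - 1, 2, grid$spacing_mm, "*"), 2, grid$origin_mm, "+")
}

# Nearest-voxel sample of the grid at n x 3 physical points.
# Points outside the array return NA.
sample_nearest <- function(grid, pts) {
  d <- dim(grid$data)
  ij <- round(world_to_index(grid, pts))
  ok <- ij[, 1] >= 1 & ij[, 1] <= d[1] & ij[, 2] >= 1 & ij[, 2] <= d[2] &
    ij[, 3] >= 1 & ij[, 3] <= d[3]
  out <- rep(NA_real_, nrow(pts))
  if (any(ok)) {
    lin <- (ij[ok, 3] - 1) * d[1] * d[2] + (ij[ok, 2] - 1) * d[1] + ij[ok, 1]
    out[ok] <- as.numeric(grid$data[lin])
  }
  out
}

# Trilinear sample of a scalar grid; outside points take `outside` value.
sample_trilinear <- function(grid, pts, outside = NA_real_) {
  d <- dim(grid$data)
  ij <- world_to_index(grid, pts)
  i0 <- pmin(pmax(floor(ij[, 1]), 1), d[1] - 1)
  j0 <- pmin(pmax(floor(ij[, 2]), 1), d[2] - 1)
  k0 <- pmin(pmax(floor(ij[, 3]), 1), d[3] - 1)
  fx <- ij[, 1] - i0; fy <- ij[, 2] - j0; fz <- ij[, 3] - k0
  inside <- ij[, 1] >= 1 & ij[, 1] <= d[1] & ij[, 2] >= 1 & ij[, 2] <= d[2] &
    ij[, 3] >= 1 & ij[, 3] <= d[3]
  at <- function(i, j, k) {
    grid$data[(k - 1) * d[1] * d[2] + (j - 1) * d[1] + i]
  }
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(i0, j0, k0) +
    fx * (1 - fy) * (1 - fz) * at(i0 + 1, j0, k0) +
    (1 - fx) * fy * (1 - fz) * at(i0, j0 + 1, k0) +
    fx * fy * (1 - fz) * at(i0 + 1, j0 + 1, k0) +
    (1 - fx) * (1 - fy) * fz * at(i0, j0, k0 + 1) +
    fx * (1 - fy) * fz * at(i0 + 1, j0, k0 + 1) +
    (1 - fx) * fy * fz * at(i0, j0 + 1, k0 + 1) +
    fx * fy * fz * at(i0 + 1, j0 + 1, k0 + 1)
  v[!inside] <- outside
  v
}

#' Convert a binary air/tissue grid to CT-like attenuation values
#'
#' Maps air voxels to -1000 and tissue voxels to 40 (Hounsfield-like
#' labels) so that threshold segmentation can be exercised on scalar data.
#'
#' @param grid a binary [voxel_grid] (air = 1, tissue = 0).
#' @param air_value,tissue_value scalar values to assign.
#' @return a scalar [voxel_grid].
#' @export
as_ct_scalar <- function(grid, air_value = -1000, tissue_value = 40) {
  stopifnot(inherits(grid, "voxel_grid"), grid$binary)
  out <- array(tissue_value, dim(grid$data))
  out[grid$data == 1L] <- air_value
  voxel_grid(out, grid$spacing_mm, grid$origin_mm, binary = FALSE)
}

#' Boundary voxel centers of a binary mask
#'
#' A mask voxel is a boundary voxel if any of its 6 face neighbours is
#' background or lies outside the array. Used for Hausdorff distances on
#' the common comparison grid.
#'
#' @param grid a binary [voxel_grid].
#' @return n x 3 matrix of boundary voxel centers in mm.
#' @export
boundary_points <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"), grid$binary)
  m <- grid$data == 1L
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  idx <- which(core & !nb, arr.ind = TRUE)
  index_to_world(grid, idx)
}

voxel_diagonal <- function(grid) sqrt(sum(grid$spacing_mm^2))

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing_mm - b$spacing_mm)) < tol &&
    max(abs(a$origin_mm - b$origin_mm)) < tol
}

#' Read and write voxel grids as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} preserving voxel spacing. The NIfTI
#' origin is stored in the qform translation.
#'
#' @param grid a [voxel_grid].
#' @param path file path (`.nii` or `.nii.gz`).
#' @rdname nifti-io
#' @export
write_nifti_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(grid$data)
  RNifti::pixdim(img) <- grid$spacing_mm
  img <- RNifti::asNifti(img)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param binary logical; interpret the voxel data as a {0,1} mask.
#' @param origin_mm origin to assign on read (the package keeps origins in
#'   its own convention rather than trusting external qforms).
#' @rdname nifti-io
#' @export
read_nifti_grid <- function(path, binary = NA, origin_mm = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim(img)[1:3])
  if (is.na(binary)) binary <- all(arr %in% c(0, 1))
  voxel_grid(arr, sp, origin_mm, binary = binary)
}
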