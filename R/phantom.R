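#' Parameters of the synthetic nasal-airway phantom
#'
#' The phantom is a single-cavity, star-convex lumen around a straight
#' centerline (the airflow / pullback axis). Its radial wall function
#' `r(theta, z)` combines a nominal radius, a Gaussian valve constriction,
#' a flattened septal side, a turbinate-like medial protrusion and a small
#' seeded roughness, so that segmentation and registration are not
#' trivially exact. Defaults are chosen to land the lumen volume in the
#' 800-2500 mm^3 range typical of adult nasal airways.
#'
#' @param length_mm axial extent along the airflow axis.
#' @param base_radius_mm nominal lumen radius.
#' @param valve_z_mm axial position of the valve constriction.
#' @param valve_depth fractional radius reduction at the valve, in `[0, 1)`.
#' @param valve_width_mm axial FWHM of the constriction.
#' @param turbinate_amp_mm amplitude of the turbinate-like wall protrusion.
#' @param septum_flatness fractional flattening of the septal side (0 = none).
#' @param roughness_mm RMS amplitude of the seeded wall roughness.
#' @param voxel_mm isotropic voxel spacing of the generated grid.
#' @param margin_mm tissue margin beyond the widest lumen extent.
#' @param probe_offset_mm in-plane (x, y) offset of the probe trajectory
#'   from the centerline.
#' @param seed RNG seed; identical parameters and seed give bit-identical
#'   phantoms.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(length_mm = 30, base_radius_mm = 4,
                           valve_z_mm = 10, valve_depth = 0.3,
                           valve_width_mm = 6, turbinate_amp_mm = 0.8,
                           septum_flatness = 0.25, roughness_mm = 0.1,
                           voxel_mm = 0.33, margin_mm = 1.5,
                           probe_offset_mm = c(0, 0), seed = 1L) {
  stopifnot_scalar(length_mm, "length_mm", positive = TRUE)
  stopifnot_scalar(base_radius_mm, "base_radius_mm", positive = TRUE)
  stopifnot_scalar(voxel_mm, "voxel_mm", positive = TRUE)
  stopifnot_scalar(valve_depth, "valve_depth")
  if (valve_depth < 0 || valve_depth >= 1)
    stop("'valve_depth' must lie in [0, 1)")
  if (valve_z_mm <= 0 || valve_z_mm >= length_mm)
    stop("'valve_z_mm' must lie strictly inside (0, length_mm)")
  stopifnot_scalar(valve_width_mm, "valve_width_mm", positive = TRUE)
  if (length(probe_offset_mm) != 2L)
    stop("'probe_offset_mm' must be length 2 (x, y)")
  structure(list(length_mm = length_mm, base_radius_mm = base_radius_mm,
                 valve_z_mm = valve_z_mm, valve_depth = valve_depth,
                 valve_width_mm = valve_width_mm,
                 turbinate_amp_mm = turbinate_amp_mm,
                 septum_flatness = septum_flatness,
                 roughness_mm = roughness_mm, voxel_mm = voxel_mm,
                 margin_mm = margin_mm,
                 probe_offset_mm = as.numeric(probe_offset_mm),
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Seeded roughness term: a fixed small set of azimuthal/axial harmonics
# with random amplitudes and phases, scaled to the requested RMS.
roughness_field <- function(params) {
  if (params$roughness_mm <= 0)
    return(function(theta, z) 0)
  coef <- with_seed(params$seed, {
    k <- sample(1:4, 6, replace = TRUE)        # azimuthal harmonic
    m <- sample(0:3, 6, replace = TRUE)        # axial harmonic
    a <- rnorm(6)
    ph <- runif(6, 0, 2 * pi)
    list(k = k, m = m, a = a / sqrt(sum(a^2) / 2), ph = ph)
  })
  L <- params$length_mm
  amp <- params$roughness_mm
  function(theta, z) {
    out <- 0
    for (i in seq_along(coef$k))
      out <- out + coef$a[i] *
        sin(coef$k[i] * theta + 2 * pi * coef$m[i] * z / L + coef$ph[i])
    amp * out
  }
}

# Lumen wall radius r(theta, z) in mm. theta and z may be vectors/arrays
# of equal shape (recycled); theta = 0 points to +x, septum at theta = pi.
phantom_radius <- function(params, theta, z, rough = roughness_field(params)) {
  rz <- params$base_radius_mm *
    (1 - params$valve_depth *
       gauss_fwhm(z, params$valve_z_mm, params$valve_width_mm))
  septum <- 1 - params$septum_flatness * pmax(cos(theta - pi), 0)^2
  turb <- params$turbinate_amp_mm *
    exp(-(angle_diff(theta, pi / 2) / 0.6)^2) *
    gauss_fwhm(z, params$length_mm / 2, params$length_mm / 1.5)
  r <- rz * septum - turb + rough(theta, z)
  pmax(r, 0.25 * params$base_radius_mm)
}

#' Probe trajectory through the lumen
#'
#' @param positions_mm n x 3 matrix of per-sample probe-tip positions.
#' @param frame_axis unit pullback direction (grid axis 3 by convention).
#' @export
probe_trajectory <- function(positions_mm, frame_axis = c(0, 0, 1)) {
  positions_mm <- as.matrix(positions_mm)
  stopifnot(ncol(positions_mm) == 3L)
  frame_axis <- frame_axis / sqrt(sum(frame_axis^2))
  structure(list(positions_mm = positions_mm, frame_axis = frame_axis),
            class = "probe_trajectory")
}

# outer radius of the probe assembly (0.86 mm OD catheter)
PROBE_RADIUS_MM <- 0.43

#' Generate a synthetic nasal-airway phantom
#'
#' Voxelizes the lumen radial function onto an isotropic binary grid
#' (air = 1, tissue = 0), extracts the boundary surface and lays a probe
#' trajectory along the centerline (optionally offset in-plane). The
#' trajectory is checked for mechanical clearance: every sample must keep
#' at least the probe radius (0.43 mm) from the wall.
#'
#' @param params a [phantom_params] object.
#' @return a list with elements `grid` ([voxel_grid]), `mesh`
#'   ([surface_mesh]), `trajectory` ([probe_trajectory]) and `params`.
#' @export
make_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  rough <- roughness_field(params)
  rmax <- params$base_radius_mm * (1 + 0.05) + 4 * params$roughness_mm
  half <- rmax + params$margin_mm
  v <- params$voxel_mm
  nxy <- 2L * ceiling(half / v) + 1L
  # slab-centered z sampling keeps the voxelized length within half a
  # voxel of length_mm, so the volume converges as voxel_mm shrinks
  nz <- max(round(params$length_mm / v), 1L)
  origin <- c(-(nxy - 1) / 2 * v, -(nxy - 1) / 2 * v, v / 2)

  # 3x3 in-plane supersampling with majority vote for sub-voxel fidelity
  xs <- origin[1] + (seq_len(nxy) - 1) * v
  xf <- as.vector(outer(c(-1, 0, 1) * v / 3, xs, "+"))
  rho <- sqrt(outer(xf^2, xf^2, "+"))
  theta <- atan2(matrix(xf, length(xf), length(xf), byrow = TRUE),
                 matrix(xf, length(xf), length(xf)))
  zs <- origin[3] + (seq_len(nz) - 1) * v
  air <- array(0L, c(nxy, nxy, nz))
  for (k in seq_len(nz)) {
    r <- phantom_radius(params, theta, zs[k], rough)
    inside <- (rho <= r) * 1L
    dim(inside) <- c(3L, nxy, 3L, nxy)
    tmp <- colSums(inside)
    air[, , k] <- (tmp[, 1, ] + tmp[, 2, ] + tmp[, 3, ] >= 5L) * 1L
  }
  grid <- voxel_grid(air, v, origin, binary = TRUE)

  # centerline trajectory sampled every 0.1 mm, spanning the slab centers
  tz <- seq(zs[1], zs[nz], by = 0.1)
  pos <- cbind(params$probe_offset_mm[1], params$probe_offset_mm[2], tz)
  th_dense <- seq(0, 2 * pi, length.out = 721)[-721]
  for (i in seq_along(tz)) {
    rwall <- phantom_radius(params, th_dense, tz[i], rough)
    wall <- cbind(rwall * cos(th_dense), rwall * sin(th_dense))
    clear <- min(sqrt((wall[, 1] - pos[i, 1])^2 +
                        (wall[, 2] - pos[i, 2])^2))
    if (clear < PROBE_RADIUS_MM)
      stop(sprintf(
        "probe clearance violated at trajectory sample %d (z = %.2f mm): %.2f mm < %.2f mm",
        i, tz[i], clear, PROBE_RADIUS_MM))
  }
  list(grid = grid, mesh = mesh_from_grid(grid),
       trajectory = probe_trajectory(pos), params = params)
}

#' Emulate surgical widening of the valve region
#'
#' Dilates the lumen in-plane (a disc structuring element of radius
#' `widen_mm`) on every slice whose axial position falls inside `region_mm`,
#' emulating the cross-sectional widening produced by spreader or
#' butterfly grafts. Dilation is monotone, so the cross-sectional area of
#' every treated slice is non-decreasing.
#'
#' @param grid binary [voxel_grid] (air = 1).
#' @param widen_mm dilation radius in mm (>= 0).
#' @param region_mm length-2 axial interval (mm along axis 3) to treat.
#' @return the widened binary [voxel_grid].
#' @export
apply_graft_widening <- function(grid, widen_mm, region_mm) {
  stopifnot(inherits(grid, "voxel_grid"), grid$binary)
  if (widen_mm < 0) stop("'widen_mm' must be >= 0")
  zs <- axis_coords(grid, 3)
  if (region_mm[1] > region_mm[2]) region_mm <- rev(region_mm)
  if (region_mm[2] < min(zs) || region_mm[1] > max(zs))
    stop("'region_mm' lies outside the grid")
  if (widen_mm == 0) return(grid)

  v <- grid$spacing_mm[1:2]
  rx <- ceiling(widen_mm / v[1]); ry <- ceiling(widen_mm / v[2])
  offs <- expand.grid(dx = -rx:rx, dy = -ry:ry)
  keep <- (offs$dx * v[1])^2 + (offs$dy * v[2])^2 <= widen_mm^2
  offs <- offs[keep, , drop = FALSE]

  d <- dim(grid$data)
  ksel <- which(zs >= region_mm[1] & zs <= region_mm[2])
  data <- grid$data
  sl <- grid$data[, , ksel, drop = FALSE]
  out <- array(0L, dim(sl))
  for (i in seq_len(nrow(offs))) {
    dx <- offs$dx[i]; dy <- offs$dy[i]
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    # clamp only copies edge voxels; the phantom keeps a tissue margin
    out <- pmax(out, sl[xs, ys, , drop = FALSE])
  }
  data[, , ksel] <- out
  voxel_grid(data, grid$spacing_mm, grid$origin_mm, binary = TRUE)
}
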