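# Shared fixtures and independent oracles, built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

# Default anatomical phantom (valve at 10 mm, septum + turbinate +
# roughness), built once per test run.
default_phantom <- function() {
  if (is.null(.fixture_cache$default))
    .fixture_cache$default <- make_phantom(phantom_params())
  .fixture_cache$default
}

# Smooth straight-cylinder phantom: analytic ground truth.
cylinder_phantom <- function(radius = 5, length = 20, voxel = 0.33,
                             offset = c(0, 0)) {
  make_phantom(phantom_params(
    length_mm = length, base_radius_mm = radius,
    valve_z_mm = length / 2, valve_depth = 0, valve_width_mm = 4,
    turbinate_amp_mm = 0, septum_flatness = 0, roughness_mm = 0,
    voxel_mm = voxel, probe_offset_mm = offset))
}

# Independent cylinder mask built directly from the implicit equation
# (does not go through the phantom module).
direct_cylinder_mask <- function(radius = 5, length = 20, voxel = 0.33,
                                 pad = 2) {
  half <- radius + pad
  xs <- seq(-half, half, by = voxel)
  nz <- floor(length / voxel) + 1L
  inplane <- outer(xs^2, xs^2, "+") <= radius^2
  arr <- array(rep(inplane * 1L, nz), c(length(xs), length(xs), nz))
  voxel_grid(arr, voxel, c(min(xs), min(xs), 0), binary = TRUE)
}

# Hand-built polar scan: constant frame content from a radius/validity
# pattern, probe on the z axis.
synthetic_scan <- function(radius, valid = rep(TRUE, length(radius)),
                           n_frames = 3L, pitch = 0.3,
                           center_xy = c(0, 0)) {
  na <- length(radius)
  r <- ifelse(valid, radius, NA_real_)
  structure(list(
    wall_radius_mm = matrix(rep(r, each = n_frames), n_frames, na),
    valid = matrix(rep(valid, each = n_frames), n_frames, na),
    aliased = matrix(FALSE, n_frames, na),
    true_dist_mm = matrix(rep(r, each = n_frames), n_frames, na),
    angles_rad = (seq_len(na) - 1) * 2 * pi / na,
    frame_positions_mm = cbind(center_xy[1], center_xy[2],
                               (seq_len(n_frames) - 1) * pitch),
    params = scan_params()), class = "polar_scan")
}

# Brute-force Dice oracle by explicit set operations on voxel indices.
brute_dice <- function(a, b) {
  ia <- which(a$data == 1L)
  ib <- which(b$data == 1L)
  if (length(ia) + length(ib) == 0) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# Brute-force symmetric Hausdorff oracle over two point sets.
brute_hausdorff <- function(pa, pb) {
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  max(max(apply(d2, 1, min)), max(apply(d2, 2, min))) |> sqrt()
}

# Dense latitude-longitude point sampling of a sphere.
sphere_points <- function(radius, n_lat = 120L, n_lon = 240L) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  g <- expand.grid(lat = lat, lon = lon)
  radius * cbind(cos(g$lat) * cos(g$lon), cos(g$lat) * sin(g$lon),
                 sin(g$lat))
}

random_mask <- function(dims = c(8, 8, 8), p = 0.35, spacing = 1) {
  arr <- array(as.integer(runif(prod(dims)) < p), dims)
  voxel_grid(arr, spacing, c(0, 0, 0), binary = TRUE)
}

rotation_error_deg <- function(Ra, Rb) {
  acos(pmin(pmax((sum(diag(t(Ra) %*% Rb)) - 1) / 2, -1), 1)) * 180 / pi
}
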