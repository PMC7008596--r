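# tilted cylinder built from its implicit equation, axis in the y-z plane
tilted_cylinder_grid <- function(radius = 5, length = 20,
                                 tilt_rad = 30 * pi / 180, voxel = 0.33) {
  u <- c(0, sin(tilt_rad), cos(tilt_rad))
  xs <- seq(-radius - 2, radius + 2, by = voxel)
  ys <- seq(-radius - 2, length * u[2] + radius + 2, by = voxel)
  zs <- seq(-radius - 2, length * u[3] + radius + 2, by = voxel)
  arr <- array(0L, c(length(xs), length(ys), length(zs)))
  px <- matrix(xs, length(xs), length(ys))
  py <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  for (k in seq_along(zs)) {
    pu <- py * u[2] + zs[k] * u[3]
    d2 <- px^2 + (py - pu * u[2])^2 + (zs[k] - pu * u[3])^2
    arr[, , k] <- (d2 <= radius^2 & pu >= 0 & pu <= length) * 1L
  }
  voxel_grid(arr, voxel, c(min(xs), min(ys), min(zs)), binary = TRUE)
}

test_that("axis-aligned resampling is the identity up to the grid frame", {
  g <- cylinder_phantom(radius = 4, length = 12)$grid
  ax <- airflow_axis(c(0, 0, 0), c(0, 0, 12))
  rs <- resample_perpendicular(g, ax, 0.33)
  expect_equal(rs$spacing_mm, rep(0.33, 3))
  expect_lt(abs(volume_mm3(rs) / volume_mm3(g) - 1), 0.01)
})

test_that("oblique resampling restores circular cross-sections", {
  g <- tilted_cylinder_grid()
  ax <- airflow_axis(c(0, 0, 0),
                     20 * c(0, sin(30 * pi / 180), cos(30 * pi / 180)))
  rs <- resample_perpendicular(g, ax, 0.33)
  prof <- csa_profile(rs)
  interior <- prof$position_mm > 3 & prof$position_mm < 17
  expect_lt(max(abs(prof$area_mm2[interior] / (pi * 25) - 1)), 0.03)
  expect_error(airflow_axis(c(1, 2, 3), c(1, 2, 3)), "degenerate")
})

test_that("threshold segmentation recovers the exact phantom air mask", {
  ph <- cylinder_phantom(radius = 4, length = 10)
  ct <- as_ct_scalar(ph$grid)              # air -1000, tissue 40
  seg <- segment_airway(ct, threshold = -500, seed_point_mm = c(0, 0, 5))
  expect_identical(seg$data, ph$grid$data)
})

test_that("detached air pockets are excluded by connectivity", {
  ph <- cylinder_phantom(radius = 4, length = 10)
  g <- ph$grid
  pocket <- g
  d <- dim(g$data)
  pocket$data[1:2, 1:2, 1:2] <- 1L         # isolated corner pocket
  seg <- segment_airway(pocket, seed_point_mm = c(0, 0, 5))
  expect_identical(seg$data, g$data)
  expect_error(segment_airway(g, seed_point_mm = g$origin_mm),
               "not in an air voxel")
  ct <- as_ct_scalar(g)
  expect_error(segment_airway(ct, threshold = -2000,
                              seed_point_mm = c(0, 0, 5)),
               "empty")
})

test_that("CSA profile conserves volume and matches the circle", {
  g <- cylinder_phantom(radius = 5, length = 12)$grid
  prof <- csa_profile(g)
  interior <- prof$position_mm > 1 & prof$position_mm < 11
  expect_lt(max(abs(prof$area_mm2[interior] / (pi * 25) - 1)), 0.02)
  expect_equal(sum(prof$area_mm2) * g$spacing_mm[3], volume_mm3(g))
})

test_that("minimum-CSA localization finds the valve and honors ties", {
  ph <- default_phantom()
  inv <- locate_inv(csa_profile(ph$grid), search_range_mm = c(4, 16))
  expect_lt(abs(inv$position_mm - 10), 0.5)

  tapering <- structure(
    data.frame(position_mm = seq(0, 10, by = 0.5),
               area_mm2 = seq(50, 30, length.out = 21)),
    class = c("csa_profile", "data.frame"))
  expect_equal(locate_inv(tapering, c(0, 10))$position_mm, 10)
  flat <- tapering; flat$area_mm2 <- rep(40, 21)
  expect_equal(locate_inv(flat, c(2, 8))$position_mm, 2)
  expect_error(locate_inv(flat, c(20, 30)), "empty search range")
})

test_that("valve position is invariant under consistent translation", {
  ph <- default_phantom()
  g <- ph$grid
  shifted <- voxel_grid(g$data, g$spacing_mm, g$origin_mm + c(5, -3, 7),
                        binary = TRUE)
  inv0 <- locate_inv(csa_profile(g), c(4, 16))
  inv1 <- locate_inv(csa_profile(shifted), c(4, 16) + 7)
  expect_equal(inv1$position_mm - inv0$position_mm, 7, tolerance = 1e-9)
  expect_equal(inv1$area_mm2, inv0$area_mm2)
})
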