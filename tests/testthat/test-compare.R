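cube_mask <- function(dims = c(14, 14, 14), lo = 3, hi = 12, spacing = 1) {
  arr <- array(0L, dims)
  arr[lo:hi, lo:hi, lo:hi] <- 1L
  voxel_grid(arr, spacing, c(0, 0, 0), binary = TRUE)
}

test_that("FOV clipping removes only posterior, cranial and caudal slack", {
  g <- cylinder_phantom(radius = 4, length = 12)$grid
  full <- clip_to_fov(g, g)
  expect_identical(full$mask$data, g$data)

  # aOCT covering only the anterior half along the airflow axis
  half <- g
  zs <- aoctair:::axis_coords(g, 3)
  half$data[, , zs >= 6] <- 0L
  clipped <- clip_to_fov(g, half)
  manual <- g
  kmax <- max(which(apply(half$data, 3, sum) > 0))
  manual$data[, , (kmax + 1):dim(g$data)[3]] <- 0L
  expect_identical(clipped$mask$data, manual$data)

  # anterior-most occupied slice is untouched by any clip
  first_slice <- function(m) min(which(apply(m, 3, sum) > 0))
  expect_identical(first_slice(clipped$mask$data), first_slice(g$data))
  empty <- voxel_grid(array(0L, dim(g$data)), g$spacing_mm, g$origin_mm,
                      binary = TRUE)
  expect_error(clip_to_fov(g, empty), "empty")
})

test_that("dice matches closed forms and the set-count oracle", {
  a <- cube_mask()
  expect_equal(dice(a, a), 1)
  disjoint <- cube_mask(dims = c(30, 14, 14), lo = 3, hi = 12)
  shifted_off <- disjoint
  shifted_off$data[] <- 0L
  shifted_off$data[16:25, 3:12, 3:12] <- 1L
  expect_equal(dice(disjoint, shifted_off), 0)

  cube10 <- cube_mask(dims = c(20, 14, 14), lo = 3, hi = 12)
  shift5 <- cube10
  shift5$data[] <- 0L
  shift5$data[8:17, 3:12, 3:12] <- 1L
  expect_equal(dice(cube10, shift5), 0.5)
  expect_equal(dice(shift5, cube10), 0.5)      # symmetry

  set.seed(42)
  for (i in 1:25) {
    x <- random_mask(); y <- random_mask()
    expect_equal(dice(x, y), brute_dice(x, y))
  }
  expect_error(dice(a, cube_mask(dims = c(10, 10, 10), lo = 2, hi = 9)),
               "geometry")
})

test_that("dice is invariant under a common axis permutation", {
  set.seed(7)
  x <- random_mask(); y <- random_mask()
  xp <- voxel_grid(aperm(x$data, c(3, 1, 2)), 1, c(0, 0, 0), binary = TRUE)
  yp <- voxel_grid(aperm(y$data, c(3, 1, 2)), 1, c(0, 0, 0), binary = TRUE)
  expect_equal(dice(xp, yp), dice(x, y))
})

test_that("hausdorff matches closed forms and the brute-force oracle", {
  a <- cube_mask()
  expect_equal(hausdorff(a, a)$hd_mm, 0)

  s5 <- sphere_points(5); s6 <- sphere_points(6)
  expect_equal(hausdorff(s5, s6)$hd_mm, 1, tolerance = 0.01)

  cube <- cube_mask(dims = c(16, 14, 14), lo = 3, hi = 12)
  cube_shift <- cube
  cube_shift$data[] <- 0L
  cube_shift$data[5:14, 3:12, 3:12] <- 1L     # 2 mm along axis 1
  hd <- hausdorff(cube, cube_shift)
  expect_equal(hd$hd_mm, 2)
  expect_equal(hd$hd_mm,
               brute_hausdorff(boundary_points(cube),
                               boundary_points(cube_shift)))
  expect_equal(hausdorff(cube_shift, cube)$hd_mm, hd$hd_mm)  # symmetry
})

test_that("hausdorff obeys the triangle inequality on random masks", {
  set.seed(11)
  for (i in 1:5) {
    pa <- boundary_points(random_mask())
    pb <- boundary_points(random_mask())
    pc <- boundary_points(random_mask())
    hab <- brute_hausdorff(pa, pb)
    hbc <- brute_hausdorff(pb, pc)
    hac <- brute_hausdorff(pa, pc)
    expect_lte(hac, hab + hbc + 1e-12)
    expect_equal(hausdorff(pa, pc)$hd_mm, hac)
  }
})

test_that("comparing a mask with itself is the metric fixed point", {
  g <- cylinder_phantom(radius = 4, length = 10)$grid
  rep <- compare_masks(g, g)
  expect_equal(rep$volume_diff_mm3, 0)
  expect_equal(rep$volume_diff_pct, 0)
  expect_equal(rep$dsc, 1)
  expect_equal(rep$hd_mm, 0)
})
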