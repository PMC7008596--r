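test_that("scan geometry reproduces the helical bookkeeping", {
  g <- scan_geometry(scan_params(rotation_hz = 20, pullback_mm_s = 6,
                                 pullback_mm = 20, aline_rate_hz = 1e5))
  expect_equal(g$pitch_mm, 0.3)
  expect_equal(g$n_frames, 67)
  expect_equal(g$alines_per_frame, 5000)
  g2 <- scan_geometry(scan_params(rotation_hz = 1, pullback_mm_s = 1,
                                  pullback_mm = 10))
  expect_equal(g2$pitch_mm, 1)
  expect_equal(g2$n_frames, 11)
  expect_equal(scan_count(4, 2, 3, 5), 120)
})

test_that("a centered probe in a cylinder detects a constant radius", {
  ph <- cylinder_phantom(radius = 5, length = 8)
  sc <- helical_scan(ph$grid, ph$trajectory,
                     scan_params(pullback_mm = 6, dropout_prob = 0,
                                 rolloff_db_per_mm = 0))
  expect_true(all(sc$valid))
  # voxelized wall sits within half a voxel of the surface, and the
  # majority-vote boundary can add up to a sub-voxel sample offset
  expect_lt(max(abs(sc$wall_radius_mm - 5)), 0.25)
  expect_equal(aliased_fraction(sc), 0)
})

test_that("an offset probe matches the analytic ray-circle root", {
  ph <- cylinder_phantom(radius = 5, length = 8, offset = c(2, 0))
  sc <- helical_scan(ph$grid, ph$trajectory,
                     scan_params(pullback_mm = 6, dropout_prob = 0,
                                 rolloff_db_per_mm = 0))
  th <- sc$angles_rad
  analytic <- -2 * cos(th) + sqrt(4 * cos(th)^2 + 21)
  err <- abs(sweep(sc$wall_radius_mm, 2, analytic))
  expect_lt(max(err[sc$valid]), 0.25)
})

test_that("walls beyond the imaging range fold over and are flagged", {
  p <- phantom_params(length_mm = 4, base_radius_mm = 14, valve_z_mm = 2,
                      valve_depth = 0, turbinate_amp_mm = 0,
                      septum_flatness = 0, roughness_mm = 0)
  ph <- make_phantom(p)
  sc <- helical_scan(ph$grid, ph$trajectory,
                     scan_params(pullback_mm = 2, dropout_prob = 0,
                                 rolloff_db_per_mm = 0, r_max_mm = 12))
  expect_equal(aliased_fraction(sc), 1)
  expect_lt(max(abs(sc$wall_radius_mm[sc$valid] - 10)), 0.25)
  expect_true(all(sc$true_dist_mm[sc$valid] > 12))
})

test_that("dropout fraction grows with the sensitivity roll-off slope", {
  ph <- cylinder_phantom(radius = 5, length = 8, offset = c(2, 0))
  frac <- vapply(c(0, 2, 3.5, 5), function(ro) {
    s <- helical_scan(ph$grid, ph$trajectory,
                      scan_params(pullback_mm = 6, dropout_prob = 0,
                                  rolloff_db_per_mm = ro,
                                  detect_floor_db = -15))
    1 - mean(s$valid)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[4], frac[1])
})

test_that("detected wall points lie on the phantom surface in 3-D", {
  ph <- default_phantom()
  sc <- helical_scan(ph$grid, ph$trajectory,
                     scan_params(dropout_prob = 0, rolloff_db_per_mm = 0))
  idx <- which(sc$valid, arr.ind = TRUE)
  r <- sc$wall_radius_mm[sc$valid]
  th <- sc$angles_rad[idx[, 2]]
  pos <- sc$frame_positions_mm[idx[, 1], , drop = FALSE]
  pts <- cbind(pos[, 1] + r * cos(th), pos[, 2] + r * sin(th), pos[, 3])
  d <- aoctair:::nn_lookup_cpp(pts, ph$mesh$vertices)$dist
  expect_lt(max(d), sqrt(3) * 0.33)
})

test_that("NURD distorts angles but preserves identity at zero amplitude", {
  ph <- cylinder_phantom(radius = 5, length = 8, offset = c(2, 0))
  sc <- helical_scan(ph$grid, ph$trajectory,
                     scan_params(pullback_mm = 6, dropout_prob = 0,
                                 rolloff_db_per_mm = 0))
  expect_identical(apply_nurd(sc, 0), sc)
  # the seeded perturbation is zero-mean over one revolution
  coef <- list(k = 1:3, a = c(0.4, -1.1, 0.7), ph = c(0.3, 2.1, 5.5))
  phi <- aoctair:::nurd_profile(sc$angles_rad, coef)
  expect_lt(abs(mean(phi)), 1e-6)
  expect_equal(max(abs(phi)), 1)
  # contour area distortion is bounded, nonzero, and grows with amplitude
  a_true <- frame_to_contour(sc, 5)$area_mm2
  mean_err <- vapply(c(0.05, 0.3), function(amp) {
    mean(vapply(1:20, function(s) {
      abs(frame_to_contour(apply_nurd(sc, amp, seed = s), 5)$area_mm2 -
            a_true)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_err[1], 0)
  expect_lt(mean_err[1], 0.2 * a_true)
  expect_gt(mean_err[2], mean_err[1])
})

test_that("scan parameter validation catches nonphysical settings", {
  expect_error(scan_params(rotation_hz = 0), "rotation_hz")
  expect_error(scan_params(dropout_prob = 1), "dropout_prob")
  ph <- cylinder_phantom(radius = 5, length = 8)
  expect_error(helical_scan(ph$grid, ph$trajectory,
                            scan_params(pullback_mm = 50)),
               "beyond the probe trajectory")
})
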