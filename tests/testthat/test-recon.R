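circle_contour <- function(radius = 5, center = c(0, 0, 0), n = 360L,
                           frame_index = 1L) {
  ang <- (seq_len(n) - 1) * 2 * pi / n
  pts <- cbind(radius * cos(ang), radius * sin(ang))
  structure(list(frame_index = frame_index, angles_rad = ang,
                 radius_mm = rep(radius, n), points_mm = pts,
                 center_mm = center, gap_spans_deg = numeric(0),
                 area_mm2 = aoctair:::polygon_area(pts)),
            class = "lumen_contour")
}

test_that("a full circle of samples yields the circle contour", {
  sc <- synthetic_scan(rep(5, 360))
  ct <- frame_to_contour(sc, 1)
  expect_lt(abs(ct$area_mm2 / (pi * 25) - 1), 0.005)
  expect_length(ct$gap_spans_deg, 0)
})

test_that("small angular gaps are interpolated, large ones chorded", {
  v30 <- rep(TRUE, 360); v30[30:59] <- FALSE
  ct30 <- frame_to_contour(synthetic_scan(rep(5, 360), v30), 1)
  expect_lt(abs(ct30$area_mm2 / (pi * 25) - 1), 0.01)
  expect_length(ct30$gap_spans_deg, 0)

  v90 <- rep(TRUE, 360); v90[30:119] <- FALSE
  ct90 <- frame_to_contour(synthetic_scan(rep(5, 360), v90), 1)
  alpha <- 91 * pi / 180              # span between surviving samples
  seg <- pi * 25 - 25 / 2 * (alpha - sin(alpha))
  expect_lt(abs(ct90$area_mm2 / seg - 1), 0.01)
  expect_equal(ct90$gap_spans_deg, 91, tolerance = 1e-9)

  few <- rep(FALSE, 360); few[1:2] <- TRUE
  expect_error(frame_to_contour(synthetic_scan(rep(5, 360), few), 1),
               "unsegmentable")
})

test_that("stacked circular contours reproduce the cylinder volume", {
  sc <- synthetic_scan(rep(5, 360), n_frames = 67L, pitch = 0.3)
  rec <- reconstruct_scan(sc)
  expect_lt(abs(volume_mm3(rec$grid) / (pi * 25 * 19.8) - 1), 0.02)
})

test_that("volume scales linearly with the spanned pullback length", {
  mk <- function(nf) {
    cts <- lapply(seq_len(nf), function(f)
      circle_contour(5, c(0, 0, (f - 1) * 0.3), frame_index = f))
    volume_mm3(contours_to_volume(cts)$grid)
  }
  v11 <- mk(11); v21 <- mk(21)
  expect_equal(v21 / v11, (20 * 0.3) / (10 * 0.3), tolerance = 0.05)
})

test_that("reconstruction is translation-equivariant", {
  shift <- c(2.5, -1.25, 3)
  cts0 <- lapply(1:11, function(f)
    circle_contour(5, c(0, 0, (f - 1) * 0.3), frame_index = f))
  cts1 <- lapply(1:11, function(f)
    circle_contour(5, shift + c(0, 0, (f - 1) * 0.3), frame_index = f))
  r0 <- contours_to_volume(cts0)$grid
  r1 <- contours_to_volume(cts1)$grid
  expect_identical(r0$data, r1$data)
  expect_equal(r1$origin_mm - r0$origin_mm, shift, tolerance = 1e-9)
})

test_that("out-of-order frames are rejected", {
  cts <- list(circle_contour(5, c(0, 0, 1)), circle_contour(5, c(0, 0, 0)))
  expect_error(contours_to_volume(cts), "out of order")
  expect_error(contours_to_volume(cts[1]), "at least 2")
})

test_that("fold-over aliasing shrinks the reconstructed volume", {
  p <- phantom_params(length_mm = 4, base_radius_mm = 14, valve_z_mm = 2,
                      valve_depth = 0, turbinate_amp_mm = 0,
                      septum_flatness = 0, roughness_mm = 0)
  ph <- make_phantom(p)
  sc <- helical_scan(ph$grid, ph$trajectory,
                     scan_params(pullback_mm = 2, dropout_prob = 0,
                                 rolloff_db_per_mm = 0, r_max_mm = 12))
  rec <- reconstruct_scan(sc)
  spanned <- pi * 14^2 * 2            # true lumen over the scanned extent
  expect_lt(volume_mm3(rec$grid), spanned)
})

test_that("clean phantom scan reconstructs the scanned lumen closely", {
  ph <- default_phantom()
  sc <- helical_scan(ph$grid, ph$trajectory,
                     scan_params(dropout_prob = 0, rolloff_db_per_mm = 0))
  rec <- reconstruct_scan(sc)
  # ground truth restricted to the scanned z extent, on the recon grid
  truth <- resample_mask(ph$grid, rigid_transform(), rec$grid)
  expect_gte(dice(rec$grid, truth), 0.95)
})
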