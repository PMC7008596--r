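#' Helical aOCT acquisition parameters
#'
#' Defaults mirror a swept-source anatomical OCT system with a 100 kHz
#' A-line rate and a 12 mm imaging range, scanned at 20 Hz rotation and
#' 6 mm/s pullback over ~20 mm (helix pitch 0.3 mm, 67 frames).
#'
#' @param rotation_hz probe rotation rate (Hz).
#' @param pullback_mm_s probe translation speed (mm/s).
#' @param pullback_mm pullback (scan) length (mm).
#' @param aline_rate_hz A-line acquisition rate (Hz).
#' @param r_max_mm maximum imaging radius; walls beyond it fold over.
#' @param rolloff_db_per_mm sensitivity roll-off slope (dB per mm of range).
#' @param detect_floor_db detection threshold relative to peak signal (dB,
#'   negative); a wall at distance `d` is missed when
#'   `-rolloff_db_per_mm * d < detect_floor_db`.
#' @param dropout_prob small per-sample probability of random dropout.
#' @param n_angles angular working resolution per frame (the physical
#'   A-line count per revolution is downsampled to this).
#' @param nurd_amp_rad NURD angular perturbation amplitude (radians)
#'   applied by [helical_scan] when nonzero.
#' @param seed RNG seed for dropout and NURD.
#' @return a `scan_params` list.
#' @export
scan_params <- function(rotation_hz = 20, pullback_mm_s = 6,
                        pullback_mm = 20, aline_rate_hz = 1e5,
                        r_max_mm = 12, rolloff_db_per_mm = 1.5,
                        detect_floor_db = -30, dropout_prob = 0.02,
                        n_angles = 360L, nurd_amp_rad = 0, seed = 1L) {
  for (nm in c("rotation_hz", "pullback_mm_s", "pullback_mm",
               "aline_rate_hz", "r_max_mm"))
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  if (rolloff_db_per_mm < 0) stop("'rolloff_db_per_mm' must be >= 0")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("'dropout_prob' must lie in [0, 1)")
  structure(list(rotation_hz = rotation_hz, pullback_mm_s = pullback_mm_s,
                 pullback_mm = pullback_mm, aline_rate_hz = aline_rate_hz,
                 r_max_mm = r_max_mm,
                 rolloff_db_per_mm = rolloff_db_per_mm,
                 detect_floor_db = detect_floor_db,
                 dropout_prob = dropout_prob,
                 n_angles = as.integer(n_angles),
                 nurd_amp_rad = nurd_amp_rad, seed = as.integer(seed)),
            class = "scan_params")
}

#' Helical scan geometry
#'
#' @param params a [scan_params] object.
#' @return list with `pitch_mm` (translation per revolution), `n_frames`
#'   (`floor(pullback / pitch) + 1`) and `alines_per_frame`.
#' @export
scan_geometry <- function(params) {
  stopifnot(inherits(params, "scan_params"))
  pitch <- params$pullback_mm_s / params$rotation_hz
  list(pitch_mm = pitch,
       n_frames = floor(params$pullback_mm / pitch) + 1L,
       alines_per_frame = round(params$aline_rate_hz / params$rotation_hz))
}

#' Total scan count of the study design
#'
#' Bookkeeping for a repeated-measures acquisition design: each donor is
#' scanned on both sides, in every session (baseline and after each
#' intervention), with several repeats.
#'
#' @param n_donors,n_sides,n_sessions,n_repeats design factors.
#' @return total number of pullback scans.
#' @export
scan_count <- function(n_donors = 4, n_sides = 2, n_sessions = 3,
                       n_repeats = 5) {
  n_donors * n_sides * n_sessions * n_repeats
}

#' Simulate a helical pullback scan
#'
#' Casts rays from the probe position in each frame's transverse plane and
#' records the first air-to-tissue crossing (first-surface detection, so
#' shadowing by proximal structures is inherent). The system's finite
#' imaging range produces fold-over: a wall at true distance `d` with
#' `r_max < d <= 2 r_max` is recorded at `2 r_max - d` and flagged
#' aliased; beyond `2 r_max` the sample is invalid. Sensitivity roll-off
#' (`-rolloff_db_per_mm * d` against `detect_floor_db`) and a small
#' uniform dropout probability produce missing samples. A nonzero
#' `nurd_amp_rad` applies nonuniform rotational distortion via
#' [apply_nurd].
#'
#' Ray marching steps at half a voxel and refines the crossing by
#' bisection, giving sub-voxel wall localization against the binary grid.
#'
#' @param grid binary [voxel_grid] (air = 1) to scan.
#' @param trajectory a [probe_trajectory]; frames are placed every pitch
#'   along the pullback axis starting at the trajectory's first sample.
#' @param params a [scan_params] object.
#' @return a `polar_scan`: list with matrices `wall_radius_mm`, `valid`,
#'   `aliased` (frames x angles), vector `angles_rad`, matrix
#'   `frame_positions_mm`, and `params`.
#' @export
helical_scan <- function(grid, trajectory, params = scan_params()) {
  stopifnot(inherits(grid, "voxel_grid"), grid$binary,
            inherits(trajectory, "probe_trajectory"),
            inherits(params, "scan_params"))
  geo <- scan_geometry(params)
  nf <- geo$n_frames
  na <- params$n_angles
  tzs <- trajectory$positions_mm[, 3]
  z0 <- tzs[1]
  fz <- z0 + (seq_len(nf) - 1) * geo$pitch_mm
  if (max(fz) > max(tzs) + 1e-9)
    stop("pullback extends beyond the probe trajectory")
  fx <- approx(tzs, trajectory$positions_mm[, 1], xout = fz, rule = 2)$y
  fy <- approx(tzs, trajectory$positions_mm[, 2], xout = fz, rule = 2)$y

  angles <- (seq_len(na) - 1) * 2 * pi / na
  ux <- cos(angles); uy <- sin(angles)
  step <- min(grid$spacing_mm) / 2
  tgrid <- seq(step, 2 * params$r_max_mm, by = step)
  nt <- length(tgrid)

  radius <- matrix(NA_real_, nf, na)
  for (f in seq_len(nf)) {
    px <- fx[f] + outer(ux, tgrid)          # na x nt
    py <- fy[f] + outer(uy, tgrid)
    pts <- cbind(as.vector(px), as.vector(py), fz[f])
    s <- matrix(sample_nearest(grid, pts), na, nt)
    tissue <- !is.na(s) & s == 0
    exited <- is.na(s)
    hit <- rowSums(tissue) > 0
    first_t <- max.col(tissue, ties.method = "first")
    # tissue must come before the ray leaves the grid
    first_na <- ifelse(rowSums(exited) > 0,
                       max.col(exited, ties.method = "first"), nt + 1L)
    hit <- hit & first_t < first_na
    if (!any(hit)) next
    lo <- tgrid[pmax(first_t - 1L, 1L)]
    hi <- tgrid[first_t]
    lo[first_t == 1L] <- 0
    for (b in 1:8) {
      mid <- (lo + hi) / 2
      pm <- cbind(fx[f] + ux * mid, fy[f] + uy * mid, fz[f])
      sm <- sample_nearest(grid, pm)
      is_air <- !is.na(sm) & sm == 1
      lo <- ifelse(is_air, mid, lo)
      hi <- ifelse(is_air, hi, mid)
    }
    d <- (lo + hi) / 2
    d[!hit] <- NA_real_
    radius[f, ] <- d
  }

  true_dist <- radius
  aliased <- !is.na(true_dist) & true_dist > params$r_max_mm
  detected <- true_dist
  detected[aliased] <- 2 * params$r_max_mm - true_dist[aliased]
  valid <- !is.na(true_dist) & true_dist <= 2 * params$r_max_mm

  # sensitivity roll-off and random dropout operate on the true range
  sig <- -params$rolloff_db_per_mm * true_dist
  drop_roll <- !is.na(true_dist) & sig < params$detect_floor_db
  drop_rand <- with_seed(params$seed,
                         matrix(runif(nf * na) < params$dropout_prob, nf, na))
  valid <- valid & !drop_roll & !drop_rand
  detected[!valid] <- NA_real_
  aliased[!valid] <- FALSE

  scan <- structure(
    list(wall_radius_mm = detected, valid = valid, aliased = aliased,
         true_dist_mm = true_dist, angles_rad = angles,
         frame_positions_mm = cbind(fx, fy, fz), params = params),
    class = "polar_scan")
  if (params$nurd_amp_rad > 0)
    scan <- apply_nurd(scan, params$nurd_amp_rad, params$seed)
  scan
}

#' @export
print.polar_scan <- function(x, ...) {
  cat(sprintf(
    "<polar_scan> %d frames x %d angles; %.1f%% valid, %.1f%% aliased\n",
    nrow(x$wall_radius_mm), ncol(x$wall_radius_mm),
    100 * mean(x$valid), 100 * mean(x$aliased)))
  invisible(x)
}

# Smooth zero-mean angular perturbation used by apply_nurd: low-order
# harmonics with seeded amplitudes/phases, normalized to unit maximum.
nurd_profile <- function(angles, coef) {
  phi <- 0
  for (i in seq_along(coef$k))
    phi <- phi + coef$a[i] * sin(coef$k[i] * angles + coef$ph[i])
  phi / max(abs(phi))
}

#' Apply nonuniform rotational distortion to a scan
#'
#' Resamples each frame's detected radii at perturbed angles
#' `theta' = theta + amp_rad * phi(theta, frame)`, where `phi` is a
#' seeded, smooth (harmonics 1-3), zero-mean angular perturbation with
#' unit maximum. Radii values are unchanged; only their angular
#' assignment is distorted, which is the geometric signature of NURD.
#'
#' @param scan a `polar_scan`.
#' @param amp_rad perturbation amplitude in radians (>= 0).
#' @param seed RNG seed for the per-frame perturbation.
#' @return the distorted `polar_scan`.
#' @export
apply_nurd <- function(scan, amp_rad, seed = scan$params$seed) {
  stopifnot(inherits(scan, "polar_scan"))
  if (amp_rad < 0) stop("'amp_rad' must be >= 0")
  if (amp_rad == 0) return(scan)
  nf <- nrow(scan$wall_radius_mm)
  angles <- scan$angles_rad
  coefs <- with_seed(seed, lapply(seq_len(nf), function(f)
    list(k = 1:3, a = rnorm(3), ph = runif(3, 0, 2 * pi))))
  out <- scan
  for (f in seq_len(nf)) {
    phi <- nurd_profile(angles, coefs[[f]])
    th2 <- angles + amp_rad * phi
    r <- scan$wall_radius_mm[f, ]
    v <- scan$valid[f, ]
    if (sum(v) < 3) next
    # value observed at distorted angle th2 is reassigned to nominal angle
    out$wall_radius_mm[f, ] <- interp_periodic(angles[v], r[v], th2)
    # validity/aliasing follow the nearest distorted sample
    near <- vapply(th2, function(a) {
      which.min(abs(angle_diff(angles, wrap_angle(a))))
    }, integer(1))
    out$valid[f, ] <- scan$valid[f, near]
    out$aliased[f, ] <- scan$aliased[f, near]
    out$wall_radius_mm[f, !out$valid[f, ]] <- NA_real_
  }
  out
}

#' Fraction of valid samples flagged as fold-over aliased
#'
#' @param scan a `polar_scan`.
#' @return fraction in `[0, 1]`.
#' @export
aliased_fraction <- function(scan) {
  stopifnot(inherits(scan, "polar_scan"))
  if (!any(scan$valid)) return(0)
  sum(scan$aliased & scan$valid) / sum(scan$valid)
}

#' Export one scan frame as a data frame
#'
#' @param scan a `polar_scan`.
#' @param frame_index 1-based frame number.
#' @return data frame with columns `angle_deg`, `radius_mm`, `valid`,
#'   `aliased`.
#' @export
frame_as_df <- function(scan, frame_index) {
  stopifnot(inherits(scan, "polar_scan"))
  data.frame(angle_deg = scan$angles_rad * 180 / pi,
             radius_mm = scan$wall_radius_mm[frame_index, ],
             valid = scan$valid[frame_index, ],
             aliased = scan$aliased[frame_index, ])
}
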