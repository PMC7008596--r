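#' Rigid transform in 3-D
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation_mm length-3 translation.
#' @return a `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation_mm = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("'rotation' must be a proper orthonormal 3x3 matrix")
  structure(list(rotation = rotation,
                 translation_mm = as.numeric(translation_mm)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param transform a `rigid_transform`.
#' @param pts n x 3 matrix of points (mm).
#' @export
transform_points <- function(transform, pts) {
  sweep(pts %*% t(transform$rotation), 2, transform$translation_mm, "+")
}

#' @rdname rigid_transform
#' @param a,b transforms; `compose_transforms(a, b)` applies `b` first.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation_mm) +
                    a$translation_mm)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.vector(t(transform$rotation) %*%
                               transform$translation_mm))
}

#' Rotation matrix about an axis
#'
#' @param axis rotation axis (any length-3 vector).
#' @param angle_rad rotation angle.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_rad) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

# Rotation angle (rad) of a rotation matrix.
rotation_angle <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
}

mesh_points <- function(x) {
  if (inherits(x, "surface_mesh")) x$vertices
  else if (is.matrix(x) && ncol(x) == 3) x
  else stop("expected a surface_mesh or an n x 3 point matrix")
}

# Area-weighted vertex normals of a surface mesh.
vertex_normals <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (c in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], mesh$faces[, c])
      ids <- as.integer(rownames(acc))
      vn[ids, d] <- vn[ids, d] + acc
    }
  }
  len <- sqrt(rowSums(vn^2)); len[len == 0] <- 1
  vn / len
}

# Best rigid transform mapping p onto q (paired rows) by Kabsch/SVD.
kabsch <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  H <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  s <- svd(H)
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  rigid_transform(R, cq - as.vector(R %*% cp))
}

# Candidate initializations: centroid alignment with identity rotation
# and with each proper principal-axes matching (4 sign assignments).
init_candidates <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  cands <- list(rigid_transform(diag(3), cq - cp))
  ep <- eigen(stats::cov(p), symmetric = TRUE)$vectors
  eq <- eigen(stats::cov(q), symmetric = TRUE)$vectors
  if (det(ep) < 0) ep[, 3] <- -ep[, 3]
  if (det(eq) < 0) eq[, 3] <- -eq[, 3]
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, s1 * s2))
    R <- eq %*% S %*% t(ep)
    cands[[length(cands) + 1L]] <-
      rigid_transform(R, cq - as.vector(R %*% cp))
  }
  cands
}

#' Rigid registration by iterative closest point
#'
#' Minimizes the mean squared distance from the moving surface's points
#' to their nearest points on the fixed surface, alternating
#' nearest-neighbour correspondence with the closed-form (Kabsch) rigid
#' update. When no `init` is supplied the fit is multi-started from the
#' identity, from centroid alignment and from the best proper
#' principal-axes matching, and the start with the lowest final RMS wins
#' (partial overlaps make a single PCA initialization unreliable). When
#' the fixed surface is a mesh, the point-to-point stage is followed by a
#' point-to-plane refinement (linearized small-angle updates against the
#' fixed vertex normals), which resolves the tangential sliding that
#' point-to-point correspondences cannot.
#'
#' @param moving,fixed [surface_mesh] objects or n x 3 point matrices.
#' @param init optional [rigid_transform] initialization (disables the
#'   multi-start).
#' @param max_iter iteration cap per start.
#' @param tol convergence threshold on the RMS improvement (mm).
#' @param n_sample number of moving points used (deterministic even
#'   subsample).
#' @param refine logical; run the point-to-plane refinement stage when
#'   the fixed surface carries normals.
#' @return the fitted `rigid_transform`, with attributes `rms_mm`,
#'   `iterations` and `converged`.
#' @export
rigid_register <- function(moving, fixed, init = NULL, max_iter = 100L,
                           tol = 1e-4, n_sample = 2000L, refine = TRUE) {
  p_all <- mesh_points(moving)
  q <- mesh_points(fixed)
  if (nrow(p_all) == 0 || nrow(q) == 0) stop("empty point set")
  sel <- unique(round(seq(1, nrow(p_all),
                          length.out = min(n_sample, nrow(p_all)))))
  p <- p_all[sel, , drop = FALSE]

  icp_run <- function(tr) {
    rms_prev <- Inf
    converged <- FALSE
    it <- 0L
    rms <- NA_real_
    while (it < max_iter) {
      it <- it + 1L
      pt <- transform_points(tr, p)
      nn <- nn_lookup_cpp(pt, q)
      rms <- sqrt(mean(nn$dist^2))
      if (rms_prev - rms < tol) {
        converged <- TRUE
        break
      }
      tr <- compose_transforms(kabsch(pt, q[nn$index, , drop = FALSE]), tr)
      rms_prev <- rms
    }
    list(tr = tr, rms = rms, it = it, converged = converged)
  }

  qn <- if (refine && inherits(fixed, "surface_mesh"))
    vertex_normals(fixed) else NULL
  plane_refine <- function(tr) {
    rms_prev <- Inf
    for (it in seq_len(max_iter)) {
      pt <- transform_points(tr, p)
      nn <- nn_lookup_cpp(pt, q)
      n <- qn[nn$index, , drop = FALSE]
      diffq <- q[nn$index, , drop = FALSE] - pt
      b <- rowSums(diffq * n)
      rms <- sqrt(mean(b^2))
      if (rms_prev - rms < tol) break
      rms_prev <- rms
      cr <- cbind(pt[, 2] * n[, 3] - pt[, 3] * n[, 2],
                  pt[, 3] * n[, 1] - pt[, 1] * n[, 3],
                  pt[, 1] * n[, 2] - pt[, 2] * n[, 1])
      A <- cbind(cr, n)
      x <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                    error = function(e) NULL)
      if (is.null(x)) break
      ang <- sqrt(sum(x[1:3]^2))
      Rs <- if (ang < 1e-12) diag(3) else rotation_about(x[1:3], ang)
      tr <- compose_transforms(rigid_transform(Rs, x[4:6]), tr)
    }
    d <- nn_lookup_cpp(transform_points(tr, p), q)$dist
    list(tr = tr, rms = sqrt(mean(d^2)))
  }

  starts <- if (is.null(init)) {
    cands <- init_candidates(p, q)
    pca_rms <- vapply(cands[-1], function(tr) {
      sqrt(mean(nn_lookup_cpp(transform_points(tr, p), q)$dist^2))
    }, numeric(1))
    list(rigid_transform(), cands[[1]], cands[-1][[which.min(pca_rms)]])
  } else list(init)
  fits <- lapply(starts, icp_run)
  if (!is.null(qn)) {
    fits <- lapply(fits, function(f) {
      ref <- plane_refine(f$tr)
      if (ref$rms < f$rms) list(tr = ref$tr, rms = ref$rms, it = f$it,
                                converged = f$converged)
      else f
    })
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rms"))]]
  if (!best$converged)
    warning("ICP did not converge within 'max_iter' iterations")
  structure(best$tr, rms_mm = best$rms, iterations = best$it,
            converged = best$converged, class = class(best$tr))
}

#' Resample a transformed binary volume onto a reference grid
#'
#' Applies a rigid transform to a mask by inverse mapping: each reference
#' voxel center is pulled back through the transform and looked up
#' nearest-neighbour in the moving mask.
#'
#' @param mask binary [voxel_grid] to transform.
#' @param transform [rigid_transform] mapping mask coordinates to
#'   reference coordinates.
#' @param reference [voxel_grid] defining the output geometry.
#' @return binary [voxel_grid] on the reference geometry.
#' @export
resample_mask <- function(mask, transform, reference) {
  stopifnot(inherits(mask, "voxel_grid"), mask$binary,
            inherits(reference, "voxel_grid"))
  d <- dim(reference$data)
  idx <- cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
               rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
               rep(seq_len(d[3]), each = d[1] * d[2]))
  world <- index_to_world(reference, idx)
  back <- transform_points(invert_transform(transform), world)
  s <- sample_nearest(mask, back)
  s[is.na(s)] <- 0
  voxel_grid(array(as.integer(s), d), reference$spacing_mm,
             reference$origin_mm, binary = TRUE)
}
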