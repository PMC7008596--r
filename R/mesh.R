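#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of coordinates in mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("'vertices' must be n x 3")
  if (ncol(faces) != 3L) stop("'faces' must be m x 3")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("'faces' index vertices outside the mesh")
  structure(list(vertices = vertices, faces = faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Extract the boundary surface of a binary voxel grid
#'
#' Builds the air/tissue interface as the set of exposed voxel faces (each
#' square face split into two triangles). Vertices lie on voxel corners,
#' so every vertex is within half a voxel diagonal of the true interface.
#'
#' @param grid a binary [voxel_grid] (air = 1).
#' @return a [surface_mesh] in mm coordinates.
#' @export
mesh_from_grid <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"), grid$binary)
  m <- grid$data == 1L
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m

  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  C1 <- C2 <- C3 <- C4 <- NULL   # integer corner coordinates per face
  for (s in shifts) {
    nb <- pad[(2:(d[1] + 1)) + s[1], (2:(d[2] + 1)) + s[2],
              (2:(d[3] + 1)) + s[3], drop = FALSE]
    dim(nb) <- d
    idx <- which(m & !nb, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    # face perpendicular to the shift axis, on the +/- side of the voxel
    ax <- which(s != 0)
    oth <- setdiff(1:3, ax)
    base <- idx - 1L                      # corner-space lower corner
    base[, ax] <- base[, ax] + as.integer(s[ax] > 0)
    c1 <- base
    c2 <- base; c2[, oth[1]] <- c2[, oth[1]] + 1L
    c3 <- base; c3[, oth[1]] <- c3[, oth[1]] + 1L
    c3[, oth[2]] <- c3[, oth[2]] + 1L
    c4 <- base; c4[, oth[2]] <- c4[, oth[2]] + 1L
    C1 <- rbind(C1, c1); C2 <- rbind(C2, c2)
    C3 <- rbind(C3, c3); C4 <- rbind(C4, c4)
  }
  if (is.null(C1)) return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))

  corner <- rbind(C1, C2, C3, C4)
  nface <- nrow(C1)
  lin <- corner[, 1] + corner[, 2] * (d[1] + 1) +
    corner[, 3] * (d[1] + 1) * (d[2] + 1)
  uniq <- sort(unique(lin))
  vid <- match(lin, uniq)
  # recover corner coordinates of the unique vertex set
  ux <- uniq %% (d[1] + 1)
  uy <- (uniq %/% (d[1] + 1)) %% (d[2] + 1)
  uz <- uniq %/% ((d[1] + 1) * (d[2] + 1))
  verts <- cbind(ux, uy, uz)
  verts <- sweep(sweep(verts - 0.5, 2, grid$spacing_mm, "*"),
                 2, grid$origin_mm, "+")
  i1 <- vid[seq_len(nface)]
  i2 <- vid[nface + seq_len(nface)]
  i3 <- vid[2 * nface + seq_len(nface)]
  i4 <- vid[3 * nface + seq_len(nface)]
  faces <- rbind(cbind(i1, i2, i3), cbind(i1, i3, i4))
  surface_mesh(verts, faces)
}

#' Taubin smoothing of a surface mesh
#'
#' Alternates a shrinking Laplacian step (`lambda`) with an inflating one
#' (`mu`) so the stair-step artifacts of voxel-face meshes are relaxed
#' without global shrinkage. Vertices stay within a voxel diagonal of the
#' original surface for the default settings.
#'
#' @param mesh a [surface_mesh].
#' @param iterations number of lambda/mu passes.
#' @param lambda,mu Taubin step sizes (`0 < lambda`, `mu < -lambda`).
#' @return the smoothed [surface_mesh].
#' @export
smooth_mesh <- function(mesh, iterations = 10L, lambda = 0.5, mu = -0.53) {
  stopifnot(inherits(mesh, "surface_mesh"))
  f <- mesh$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  v <- mesh$vertices
  deg <- tabulate(edges[, 1], nbins = nrow(v))
  deg[deg == 0] <- 1
  step <- function(v, w) {
    nb <- rowsum(v[edges[, 2], , drop = FALSE], edges[, 1],
                 reorder = TRUE)
    full <- matrix(0, nrow(v), 3)
    full[as.integer(rownames(nb)), ] <- nb
    v + w * (full / deg - v)
  }
  for (i in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  surface_mesh(v, f)
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a [surface_mesh].
#' @param path output file path.
#' @param name solid name recorded in the file.
#' @export
write_stl <- function(mesh, path, name = "aoctair") {
  stopifnot(inherits(mesh, "surface_mesh"))
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  tri <- paste0(
    sprintf("facet normal %g %g %g\n", nrm[, 1], nrm[, 2], nrm[, 3]),
    "outer loop\n",
    sprintf("vertex %g %g %g\n", v1[, 1], v1[, 2], v1[, 3]),
    sprintf("vertex %g %g %g\n", v2[, 1], v2[, 2], v2[, 3]),
    sprintf("vertex %g %g %g\n", v3[, 1], v3[, 2], v3[, 3]),
    "endloop\nendfacet")
  writeLines(tri, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
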