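# Iso-surface reconstruction and mesh utilities.
#
# Meshes are extracted by marching tetrahedra on the (optionally
# Gaussian-smoothed) binary field at level 0.5. Masks are always padded
# by two background voxels before meshing so surfaces touching the array
# border still close; meshes from interior masks are watertight with
# outward-consistent winding. An optional implicit cotangent fairing
# step (solve (M + t L) X = M V) removes lattice-frequency vertex noise
# for curvature work while leaving um-scale geometry in place.

#' Reconstruct a triangular surface mesh from a binary mask
#'
#' @param mask logical 3D array with `voxel_size` attribute (um)
#' @param smooth_sigma Gaussian pre-smoothing of the 0/1 field, in voxels.
#'   1 (default) is right for smooth biological shapes; use 0 to preserve
#'   sharp edges (boxes, plates) exactly.
#' @param fair_t implicit fairing time in um^2 (0 disables). Use ~10 when
#'   the mesh feeds curvature estimation.
#' @param level iso-level of the 0/1 field
#' @return object of class `surface_mesh`: `vertices` (N x 3 um), `faces`
#'   (M x 3, 1-based, counter-clockwise from outside), `voxel_size`, and
#'   empty tag/curvature slots (`region`, `coverage`, `H`)
#' @export
mesh_from_mask <- function(mask, smooth_sigma = 1, fair_t = 0, level = 0.5) {
  vs <- .vox_attr(mask)
  if (!any(mask)) stop("cannot mesh an empty mask")
  pad <- 2L
  d <- dim(mask)
  dp <- d + 2L * pad
  field <- array(0, dp)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  if (smooth_sigma > 0)
    field <- smooth_gaussian_3d_cpp(field, dp, rep(smooth_sigma, 3))
  res <- marching_tetrahedra_cpp(field, dp, level, vs, -pad * vs)
  if (nrow(res$vertices) == 0) stop("iso-surface is empty at this level")
  mesh <- structure(list(vertices = res$vertices, faces = res$faces,
                         voxel_size = vs, region = NULL, coverage = NULL,
                         H = NULL),
                    class = "surface_mesh")
  if (fair_t > 0) mesh <- fair_mesh(mesh, fair_t)
  mesh
}

# cotangent weights, face normals and areas shared by fairing, curvature
# and area computations
.face_geometry <- function(V, F) {
  i1 <- F[, 1]; i2 <- F[, 2]; i3 <- F[, 3]
  p1 <- V[i1, , drop = FALSE]
  p2 <- V[i2, , drop = FALSE]
  p3 <- V[i3, , drop = FALSE]
  e23 <- p3 - p2; e31 <- p1 - p3; e12 <- p2 - p1
  n <- cbind(e12[, 2] * (-e31)[, 3] - e12[, 3] * (-e31)[, 2],
             e12[, 3] * (-e31)[, 1] - e12[, 1] * (-e31)[, 3],
             e12[, 1] * (-e31)[, 2] - e12[, 2] * (-e31)[, 1])
  dblA <- sqrt(rowSums(n^2))
  degen <- dblA == 0
  dblA[degen] <- NA
  dot <- function(u, v) rowSums(u * v)
  list(i1 = i1, i2 = i2, i3 = i3, normal = n, dblA = dblA, degenerate = degen,
       cot1 = dot(-e31, e12) / dblA,
       cot2 = dot(-e12, e23) / dblA,
       cot3 = dot(-e23, e31) / dblA,
       l12 = rowSums(e12^2), l23 = rowSums(e23^2), l31 = rowSums(e31^2))
}

.cot_laplacian <- function(V, F) {
  g <- .face_geometry(V, F)
  nv <- nrow(V)
  ii <- c(g$i2, g$i3, g$i3, g$i1, g$i1, g$i2)
  jj <- c(g$i3, g$i2, g$i1, g$i3, g$i2, g$i1)
  ww <- c(g$cot1, g$cot1, g$cot2, g$cot2, g$cot3, g$cot3) / 2
  ok <- is.finite(ww)
  W <- sparseMatrix(i = ii[ok], j = jj[ok], x = ww[ok], dims = c(nv, nv))
  mass <- numeric(nv)
  acc <- rowsum(rep(g$dblA / 6, 3), c(g$i1, g$i2, g$i3), na.rm = TRUE)
  mass[as.integer(rownames(acc))] <- acc       # barycentric vertex areas
  list(W = W, mass = mass, geom = g)
}

#' Implicit cotangent fairing of a mesh
#'
#' One backward-Euler step of Laplace-Beltrami smoothing,
#' `(M + t L) X = M V`, with the cotangent stiffness L and barycentric
#' lumped mass M. `t` (um^2) sets the squared length scale below which
#' detail is attenuated; voxelization noise disappears around `t = 10`
#' for micrometre voxels while 100-um vessels shift negligibly.
#'
#' @param mesh `surface_mesh`
#' @param t fairing time (um^2)
#' @return faired mesh (tags preserved, curvature slot cleared)
#' @export
fair_mesh <- function(mesh, t = 10) {
  cl <- .cot_laplacian(mesh$vertices, mesh$faces)
  nv <- nrow(mesh$vertices)
  L <- Diagonal(x = Matrix::rowSums(cl$W)) - cl$W
  A <- Matrix::forceSymmetric(Diagonal(x = cl$mass) + t * L)
  X <- Matrix::solve(A, cl$mass * mesh$vertices)
  mesh$vertices <- as.matrix(X)
  mesh$H <- NULL
  mesh
}

# vertex indices on boundary or non-manifold edges (H undefined there)
.irregular_vertices <- function(F, nv) {
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bad_keys <- names(cnt)[cnt != 2]
  if (!length(bad_keys)) return(integer())
  parts <- strsplit(bad_keys, " ", fixed = TRUE)
  unique(as.integer(unlist(parts)))
}

# number of undirected edges bounded by != 2 faces (0 for watertight)
.open_edge_count <- function(F) {
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  sum(cnt != 2)
}

# map vertex coordinates to 1-based voxel indices (floor convention,
# clamped to the array bounds)
.vertex_voxels <- function(mesh, dims, warn = TRUE) {
  vs <- mesh$voxel_size
  idx <- floor(sweep(mesh$vertices, 2, vs, "/")) + 1
  out_of_bounds <- idx < 1 | idx > matrix(dims, nrow(idx), 3, byrow = TRUE)
  if (warn && any(out_of_bounds))
    warning(sum(rowSums(out_of_bounds) > 0),
            " vertices map outside the voxel grid; clamped")
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1), dims[a])
  cbind(idx[, 1], idx[, 2], idx[, 3])
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  if (!is.null(x$region))
    cat("  region tags:", sum(x$region == "sprout"), "sprout /",
        sum(x$region == "parent"), "parent\n")
  if (!is.null(x$coverage))
    cat("  coverage tags:", sum(x$coverage == "covered"), "covered\n")
  if (!is.null(x$H))
    cat("  mean curvature: median",
        signif(median(x$H, na.rm = TRUE), 4), "1/um\n")
  invisible(x)
}
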