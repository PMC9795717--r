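# Discrete mean curvature on triangular meshes.
#
# The mean-curvature normal at vertex i is K_i = sum_j w_ij (x_i - x_j)
# with cotangent weights w_ij = (cot a_ij + cot b_ij) / 2. Projected on
# the outward vertex normal and divided by twice the vertex area it
# yields the signed mean curvature; the sign convention makes convex
# bulges negative and concave pits positive (a solid sphere of radius r
# has H = -1/r everywhere, a solid cylinder's lateral surface -1/(2r)).
# Vertex areas are barycentric (one third of each incident triangle):
# on lattice-extracted meshes the Meyer mixed-Voronoi allocation is
# strongly biased by the many obtuse triangles, while the barycentric
# form keeps the median unbiased (the analytic-primitive oracles in the
# test suite anchor this choice).

#' Per-vertex signed mean curvature
#'
#' Boundary and non-manifold vertices get `NA` (their count is reported
#' in the `n_invalid` attribute); degenerate faces are skipped.
#'
#' @param mesh `surface_mesh` (ideally faired; see [fair_mesh()])
#' @return the mesh with per-vertex `H` (1/um) filled in
#' @export
mean_curvature <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  nv <- nrow(V)
  cl <- .cot_laplacian(V, F)
  K <- V * Matrix::rowSums(cl$W) - as.matrix(cl$W %*% V)
  g <- cl$geom
  idx <- c(g$i1, g$i2, g$i3)
  NN <- matrix(0, nv, 3)
  acc <- rowsum(rbind(g$normal, g$normal, g$normal), idx, na.rm = TRUE)
  NN[as.integer(rownames(acc)), ] <- acc
  nl <- sqrt(rowSums(NN^2))
  nl[nl == 0] <- 1
  NN <- NN / nl
  H <- -rowSums(K * NN) / (2 * cl$mass)
  H[cl$mass == 0] <- NA
  irregular <- .irregular_vertices(F, nv)
  H[irregular] <- NA
  mesh$H <- H
  attr(mesh$H, "n_invalid") <- sum(is.na(H))
  mesh
}

.filter_vertices <- function(mesh, tag_filter) {
  switch(tag_filter,
    all = rep(TRUE, nrow(mesh$vertices)),
    parent = ,
    sprout = {
      if (is.null(mesh$region)) stop("mesh has no region tags")
      mesh$region == tag_filter
    },
    covered = ,
    uncovered = {
      if (is.null(mesh$coverage)) stop("mesh has no coverage tags")
      mesh$coverage == tag_filter
    },
    stop("unknown tag filter: ", tag_filter))
}

#' Histogram and median of mean curvature over a tagged vertex subset
#'
#' @param mesh mesh with `H` computed (see [mean_curvature()])
#' @param tag_filter `"all"`, `"parent"`, `"sprout"`, `"covered"` or
#'   `"uncovered"`
#' @param bins number of bins, or an explicit vector of break points
#'   (1/um)
#' @return object of class `curvature_histogram`: `breaks`, `counts`,
#'   `median`, `n`, `tag_filter`
#' @export
curvature_histogram <- function(mesh, tag_filter = "all", bins = 50) {
  if (is.null(mesh$H)) stop("compute mean_curvature() first")
  sel <- .filter_vertices(mesh, tag_filter) & !is.na(mesh$H)
  h <- mesh$H[sel]
  if (!length(h)) stop("no valid vertices match filter '", tag_filter, "'")
  breaks <- if (length(bins) > 1) bins else if (min(h) == max(h))
    c(min(h) - 0.5, max(h) + 0.5) else
    seq(min(h), max(h), length.out = bins + 1)
  if (min(h) < min(breaks) || max(h) > max(breaks))
    stop("explicit breaks do not span the curvature range")
  cnt <- graphics::hist(h, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)$counts
  structure(list(breaks = breaks, counts = cnt, median = median(h),
                 n = length(h), tag_filter = tag_filter),
            class = "curvature_histogram")
}
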