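# Geometric maturity indices on tagged meshes: surface area (total and
# per tag), enclosed volume by signed tetrahedra, sprout range along the
# axis perpendicular to the vessel, MSC coverage ratio, and surface
# roughness (area / volume, 1/um) as a maturity index.

# triangle selection by tags with the majority rule: a face counts for a
# tag when at least two of its three vertices carry it
.face_selector <- function(mesh, region = NULL, coverage = NULL) {
  F <- mesh$faces
  sel <- rep(TRUE, nrow(F))
  if (!is.null(region) && region != "all") {
    if (is.null(mesh$region)) stop("mesh has no region tags")
    m <- matrix(mesh$region[F] == region, nrow(F), 3)
    sel <- sel & rowSums(m) >= 2
  }
  if (!is.null(coverage) && coverage != "all") {
    if (is.null(mesh$coverage)) stop("mesh has no coverage tags")
    m <- matrix(mesh$coverage[F] == coverage, nrow(F), 3)
    sel <- sel & rowSums(m) >= 2
  }
  sel
}

.area_by <- function(mesh, region = NULL, coverage = NULL) {
  g <- .face_geometry(mesh$vertices, mesh$faces)
  area <- g$dblA / 2
  sel <- .face_selector(mesh, region, coverage) & !g$degenerate
  structure(sum(area[sel], na.rm = TRUE),
            n_degenerate = sum(g$degenerate))
}

#' Total surface area of a (tag-filtered) mesh
#'
#' Sum of triangle areas over faces whose vertices satisfy the filter
#' (majority rule: at least 2 of 3 vertices). Degenerate zero-area faces
#' are skipped; their count is attached as attribute `n_degenerate`.
#'
#' @param mesh `surface_mesh`
#' @param tag_filter `"all"`, `"parent"`, `"sprout"`, `"covered"`,
#'   `"uncovered"`
#' @return area in um^2
#' @export
surface_area <- function(mesh, tag_filter = "all") {
  if (tag_filter %in% c("parent", "sprout"))
    .area_by(mesh, region = tag_filter)
  else if (tag_filter %in% c("covered", "uncovered"))
    .area_by(mesh, coverage = tag_filter)
  else if (tag_filter == "all")
    .area_by(mesh)
  else stop("unknown tag filter: ", tag_filter)
}

#' Enclosed volume of a watertight mesh
#'
#' Sum of signed tetrahedron volumes `det(v1, v2, v3) / 6` over faces
#' (translation-invariant for closed surfaces); the absolute value is
#' returned. A non-watertight mesh is an error reporting the number of
#' open edges.
#'
#' @param mesh `surface_mesh`
#' @return volume in um^3
#' @export
enclosed_volume <- function(mesh) {
  open_edges <- .open_edge_count(mesh$faces)
  if (open_edges > 0)
    stop("mesh is not watertight (", open_edges, " open edges)")
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  vol6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(vol6)) / 6
}

#' Sprout range along the y axis
#'
#' The spatial distance between the highest and lowest sprout-tagged
#' vertices perpendicular to the vessel axis (vessel along x by
#' convention). When all sprout vertices lie on one side of the parent
#' axis the one-sided extent is returned and flagged; with no sprout
#' vertices the range is 0 (flagged).
#'
#' @param mesh mesh with region tags
#' @return list: `range_um`, `one_sided`, `no_sprout`
#' @export
sprout_range <- function(mesh) {
  if (is.null(mesh$region)) stop("mesh has no region tags")
  sy <- mesh$vertices[mesh$region == "sprout", 2]
  if (!length(sy))
    return(list(range_um = 0, one_sided = TRUE, no_sprout = TRUE))
  center <- median(mesh$vertices[mesh$region == "parent", 2])
  if (!is.finite(center)) center <- median(mesh$vertices[, 2])
  one_sided <- all(sy >= center) || all(sy <= center)
  list(range_um = max(sy) - min(sy), one_sided = one_sided,
       no_sprout = FALSE)
}

#' MSC coverage ratio
#'
#' Covered surface area divided by total surface area, optionally
#' restricted to the sprout region.
#'
#' @param mesh mesh with coverage tags (and region tags for
#'   `scope = "sprout"`)
#' @param scope `"all"` or `"sprout"`
#' @return fraction in \[0, 1\]
#' @export
coverage_ratio <- function(mesh, scope = c("all", "sprout")) {
  scope <- match.arg(scope)
  region <- if (scope == "sprout") "sprout" else NULL
  total <- .area_by(mesh, region = region)
  if (total == 0) stop("zero surface area in scope '", scope, "'")
  covered <- .area_by(mesh, region = region, coverage = "covered")
  as.numeric(covered / total)
}

#' Morphometry report for one sample
#'
#' @param mesh tagged mesh (region and, if available, coverage)
#' @param parent_mesh optional mesh of the parent region alone; when
#'   given, `sprout_volume = enclosed_volume(mesh) -
#'   enclosed_volume(parent_mesh)`
#' @param sample_id identifier copied into the row
#' @return one-row data.frame: sprout_range, areas (total/parent/sprout),
#'   enclosed volume, sprout volume, roughness (area/volume, 1/um),
#'   coverage ratio
#' @export
morphometry_report <- function(mesh, parent_mesh = NULL, sample_id = "sample") {
  sr <- sprout_range(mesh)
  area_total <- as.numeric(surface_area(mesh))
  area_parent <- if (!is.null(mesh$region))
    as.numeric(surface_area(mesh, "parent")) else NA_real_
  area_sprout <- if (!is.null(mesh$region))
    as.numeric(surface_area(mesh, "sprout")) else NA_real_
  vol <- enclosed_volume(mesh)
  sprout_vol <- if (!is.null(parent_mesh))
    vol - enclosed_volume(parent_mesh) else NA_real_
  cov <- if (!is.null(mesh$coverage)) coverage_ratio(mesh) else NA_real_
  data.frame(sample_id = sample_id,
             sprout_range_um = sr$range_um,
             one_sided = sr$one_sided,
             surface_area_um2 = area_total,
             parent_area_um2 = area_parent,
             sprout_area_um2 = area_sprout,
             enclosed_volume_um3 = vol,
             sprout_volume_um3 = sprout_vol,
             roughness_per_um = area_total / vol,
             coverage_ratio = cov)
}
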