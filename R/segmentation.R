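# Vertex tagging: parent vessel vs sprout, and MSC-covered vs uncovered.
#
# The parent region is recovered by morphological opening of the filled
# vessel mask with a ball of 0.6 x nominal radius: sprouts (thinner than
# the ball) are erased, the parent tube survives. The voxel region
# outside the parent is then eroded by `erosion_px` voxels, and mesh
# vertices falling in the eroded outside-region -- i.e. farther than
# `erosion_px` voxels from the parent -- are tagged as sprout. Coverage
# tagging reads the binarized green channel at each vertex's voxel.

#' Recover the parent-vessel voxel region
#'
#' Morphological opening (Euclidean-ball erosion then dilation, via exact
#' distance transforms) of the hole-filled mask with a ball of radius
#' `0.6 * nominal_radius`, keeping the largest component. Requires
#' isotropic voxels (resample first; see [resample_isotropic()]).
#'
#' @param mask binary mask of the vessel (shell or solid; holes are
#'   filled internally)
#' @param nominal_radius nominal parent-vessel radius (um); the default
#'   100 um matches the needle-templated vessel
#' @param vessel_axis axis along which the vessel leaves the stack (its
#'   open lumen ends are treated as interior when filling); 1 = x
#' @return binary mask of the parent region
#' @export
define_parent_region <- function(mask, nominal_radius = 100,
                                 vessel_axis = 1) {
  if (nominal_radius <= 0) stop("nominal_radius must be positive")
  vs <- .vox_attr(mask)
  if (max(vs) - min(vs) > 1e-9)
    stop("define_parent_region requires isotropic voxels; resample first")
  filled <- fill_mask_holes(mask, exclude_axes = vessel_axis)
  r_vox <- 0.6 * nominal_radius / vs[1]
  d <- dim(mask)
  # erosion: keep voxels farther than r from background
  dist2_bg <- edt_sq_cpp(as.logical(filled), d, c(1, 1, 1))
  eroded <- array(dist2_bg > r_vox^2, d)
  if (!any(eroded))
    stop("opening removed the whole mask; try a smaller nominal_radius")
  # dilation: voxels within r of the eroded core
  dist2_core <- edt_sq_cpp(!eroded, d, c(1, 1, 1))
  opened <- array(eroded | dist2_core <= r_vox^2, d)
  attr(opened, "voxel_size") <- vs
  largest_component(opened)
}

#' Tag mesh vertices as parent vessel or sprout
#'
#' The voxel region outside the parent is eroded by `erosion_px` voxels
#' (Euclidean ball); vertices inside the eroded outside-region -- i.e.
#' farther than `erosion_px` voxels from any parent voxel -- become
#' `"sprout"`, the rest `"parent"`. With `erosion_px = 0` every vertex
#' off the parent region is a sprout vertex.
#'
#' @param mesh `surface_mesh` in the same voxel frame as `parent_region`
#' @param parent_region binary mask from [define_parent_region()]
#' @param erosion_px erosion depth in voxels (isotropic)
#' @return mesh with `region` tags (`"parent"` / `"sprout"`)
#' @export
tag_parent_vs_sprout <- function(mesh, parent_region, erosion_px = 10) {
  stopifnot(inherits(mesh, "surface_mesh"), erosion_px >= 0)
  d <- dim(parent_region)
  dist2 <- edt_sq_cpp(!parent_region, d, c(1, 1, 1))
  vx <- .vertex_voxels(mesh, d)
  dv <- dist2[vx]
  mesh$region <- ifelse(dv > erosion_px^2, "sprout", "parent")
  mesh
}

#' Tag mesh vertices as MSC-covered or uncovered
#'
#' A vertex whose containing voxel has positive binarized green signal is
#' `"covered"`, otherwise `"uncovered"`.
#'
#' @param mesh `surface_mesh`
#' @param green_mask binarized green-channel mask (same voxel frame)
#' @return mesh with `coverage` tags
#' @export
tag_msc_coverage <- function(mesh, green_mask) {
  stopifnot(inherits(mesh, "surface_mesh"))
  d <- dim(green_mask)
  vx <- .vertex_voxels(mesh, d)
  mesh$coverage <- ifelse(green_mask[vx], "covered", "uncovered")
  mesh
}
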