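# 3D preprocessing: median filtering + global thresholding, connected
# components, hole filling, and resampling to isotropic voxels so that
# pixel-denominated morphology (e.g. "eroded by ten pixels") is
# direction-independent.

.vox_attr <- function(x) {
  v <- attr(x, "voxel_size")
  if (is.null(v)) stop("object carries no voxel_size attribute")
  v
}

#' Binarize one channel of a volume stack
#'
#' A 3D median filter with cubic neighbourhood `(2 * median_radius + 1)^3`
#' followed by a global threshold (Otsu on the filtered intensities, or a
#' fixed value so that the same settings can be reused across samples).
#'
#' @param vol a `volume_stack` (see [make_vessel_phantom_3d()]) or a 3D
#'   array with a `voxel_size` attribute
#' @param channel which channel to binarize when `vol` is a stack
#' @param median_radius median-filter radius in voxels; 0 = threshold only
#' @param threshold `"otsu"` or `"fixed"`
#' @param threshold_value required when `threshold = "fixed"`
#' @return logical array (binary mask) with `voxel_size` attribute
#' @export
preprocess_volume <- function(vol, channel = "red", median_radius = 1,
                              threshold = c("otsu", "fixed"),
                              threshold_value = NULL) {
  threshold <- match.arg(threshold)
  if (inherits(vol, "volume_stack")) {
    arr <- vol[[channel]]
    if (is.null(arr)) stop("channel ", channel, " not present")
    vs <- vol$voxel_size
  } else {
    arr <- vol
    vs <- .vox_attr(vol)
  }
  dims <- dim(arr)
  if (median_radius > 0)
    arr <- median_filter_3d_cpp(arr, dims, as.integer(median_radius))
  th <- if (threshold == "otsu") .otsu_threshold(as.numeric(arr)) else {
    if (is.null(threshold_value)) stop("threshold_value required for fixed")
    threshold_value
  }
  mask <- array(arr > th, dims)
  if (!any(mask)) stop("binarization produced an all-background mask")
  attr(mask, "voxel_size") <- vs
  mask
}

#' Keep only the largest 26-connected component
#'
#' Used to extract the parent vessel structure connected with its sprouts
#' while discarding detached debris.
#'
#' @param mask logical 3D array with `voxel_size`
#' @return mask of the same shape retaining only the largest component
#' @export
largest_component <- function(mask) {
  vs <- .vox_attr(mask)
  if (!any(mask)) stop("empty mask")
  lab <- label_components_cpp(as.logical(mask), dim(mask))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  out <- array(lab == keep, dim(mask))
  attr(out, "voxel_size") <- vs
  out
}

#' Fill interior cavities of a mask
#'
#' Background components not connected to the array border are interior
#' cavities (e.g. the lumen inside the endothelial shell) and are filled.
#' A vessel whose axis crosses the stack boundary has a lumen open at
#' those faces; exclude that axis so the lumen still counts as interior.
#'
#' @param mask logical 3D array with `voxel_size`
#' @param exclude_axes axes (1 = x, 2 = y, 3 = z) whose border faces are
#'   ignored when deciding what is connected to the outside
#' @return filled mask
#' @export
fill_mask_holes <- function(mask, exclude_axes = integer()) {
  vs <- .vox_attr(mask)
  bg <- !mask
  lab <- label_components_cpp(as.logical(bg), dim(mask))
  d <- dim(mask)
  border_labels <- unique(c(
    if (!(1 %in% exclude_axes)) lab[c(1, d[1]), , ],
    if (!(2 %in% exclude_axes)) lab[, c(1, d[2]), ],
    if (!(3 %in% exclude_axes)) lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0L]
  out <- array(mask | (lab > 0L & !(lab %in% border_labels)), d)
  attr(out, "voxel_size") <- vs
  out
}

#' Resample a volume or mask to isotropic voxels
#'
#' Linear interpolation along each axis whose pitch differs from the
#' target (default: the smallest axis pitch). Masks are interpolated as
#' 0/1 fields and re-thresholded at 0.5.
#'
#' @param vol 3D array with `voxel_size` attribute (numeric or logical)
#' @param target target isotropic pitch (um)
#' @return resampled array with updated `voxel_size`
#' @export
resample_isotropic <- function(vol, target = NULL) {
  vs <- .vox_attr(vol)
  if (is.null(target)) target <- min(vs)
  was_mask <- is.logical(vol)
  arr <- vol
  storage.mode(arr) <- "double"
  for (axis in 1:3) {
    if (isTRUE(all.equal(vs[axis], target))) next
    arr <- .interp_axis(arr, axis, vs[axis], target)
    vs[axis] <- target
  }
  if (was_mask) arr <- arr >= 0.5
  arr <- array(arr, dim(arr))
  attr(arr, "voxel_size") <- rep(target, 3)
  arr
}

# linear interpolation along one axis at voxel-centre positions
.interp_axis <- function(arr, axis, d_old, d_new) {
  n_old <- dim(arr)[axis]
  extent <- n_old * d_old
  n_new <- max(2L, as.integer(round(extent / d_new)))
  pos <- (seq_len(n_new) - 0.5) * d_new          # world coords of new centres
  f <- pos / d_old - 0.5 + 1                      # fractional old index (1-based)
  f <- pmin(pmax(f, 1), n_old)
  i0 <- pmin(floor(f), n_old - 1)
  w <- f - i0
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dims <- dim(a)
  a <- matrix(a, dims[1], dims[2] * dims[3])
  out <- a[i0, , drop = FALSE] * (1 - w) + a[i0 + 1, , drop = FALSE] * w
  out <- array(out, c(n_new, dims[2], dims[3]))
  aperm(out, order(perm))
}
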