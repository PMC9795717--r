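# Synthetic 3D vessel phantoms with full ground truth.
#
# The phantom emulates the chip geometry: a horizontal parent vessel of
# ~200 um diameter (needle-templated lumen), sprouts branching from its
# wall, ellipsoidal MSCs attached to vessel or sprout surfaces, PSF blur
# and mixed Poisson/Gaussian noise. Every voxel carries a ground-truth
# label so downstream segmentation and morphometry can be scored exactly.

#' Specify one sprout on the parent vessel wall
#'
#' A sprout is a tapered tube of length `length` growing from a base point
#' on the vessel wall. The base point is parameterized by its axial
#' position `base_x` (um along the vessel axis) and the polar angle
#' `base_angle` around the axis (90 = +y "up", 270 = -y "down"). Its local
#' radius is `base_radius + (tip_radius - base_radius) * s/length +
#' roughness_amplitude * sin(2*pi*s/roughness_wavelength)` at arc position
#' `s`, giving an analytically known surface for rough- vs smooth-sprout
#' comparisons.
#'
#' @param base_x axial position of the base point (um)
#' @param base_angle polar angle of the base point around the vessel axis
#'   (degrees; 90 points along +y)
#' @param length sprout length (um)
#' @param base_radius,tip_radius sprout radii at base and tip (um)
#' @param roughness_amplitude,roughness_wavelength sinusoidal radial
#'   modulation (um); amplitude 0 gives a smooth (co-culture-like) sprout
#' @return a `sprout_spec` list
#' @export
sprout_spec <- function(base_x, base_angle = 90, length = 150,
                        base_radius = 40, tip_radius = 25,
                        roughness_amplitude = 0, roughness_wavelength = 40) {
  stopifnot(length > 0, base_radius > 0, tip_radius > 0,
            roughness_wavelength > 0, roughness_amplitude >= 0)
  if (roughness_amplitude >= min(base_radius, tip_radius))
    stop("roughness_amplitude must be smaller than the sprout radii")
  structure(list(base_x = base_x, base_angle = base_angle, length = length,
                 base_radius = base_radius, tip_radius = tip_radius,
                 roughness_amplitude = roughness_amplitude,
                 roughness_wavelength = roughness_wavelength),
            class = "sprout_spec")
}

#' Specify one ellipsoidal MSC
#'
#' @param center centre (x, y, z) in um, or `NULL` when `attached_to`
#'   places the cell automatically on a surface
#' @param semi_axes ellipsoid semi-axes (um), major first
#' @param axis unit direction of the major axis
#' @param attached_to `"none"`, `"parent"`, or `"sprout_<i>"`; attached
#'   cells are centred on the named surface so that they straddle it
#' @param attach_s,attach_angle for attached cells: arc position along the
#'   sprout (fraction of length) and polar angle on the parent wall
#' @return an `msc_spec` list
#' @export
msc_spec <- function(center = NULL, semi_axes = c(25, 12, 12),
                     axis = c(1, 0, 0), attached_to = "none",
                     attach_s = 0.5, attach_angle = 90) {
  stopifnot(all(semi_axes > 0), length(semi_axes) == 3)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(center = center, semi_axes = semi_axes, axis = axis,
                 attached_to = attached_to, attach_s = attach_s,
                 attach_angle = attach_angle),
            class = "msc_spec")
}

#' Specify a 3D vessel phantom
#'
#' Defaults emulate the chip: a 200 um-diameter parent vessel (radius 100)
#' along +x, wall rendered as a 10 um-thick endothelial shell.
#'
#' @param vessel_radius parent vessel outer radius (um)
#' @param domain_size domain extent (x, y, z) in um
#' @param voxel_size voxel pitch (dx, dy, dz) in um
#' @param wall_thickness endothelial shell thickness (um)
#' @param sprouts list of [sprout_spec()] objects
#' @param mscs list of [msc_spec()] objects
#' @param psf_sigma Gaussian PSF sigma (um); 0 disables blur
#' @param gaussian_sd read-noise standard deviation (intensity units)
#' @param poisson_scale photon scale for Poisson noise; 0 disables
#' @param seed integer seed; fixes the output bit-exactly
#' @return a `phantom_spec_3d` list
#' @export
phantom_spec_3d <- function(vessel_radius = 100,
                            domain_size = c(400, 400, 300),
                            voxel_size = c(2, 2, 2),
                            wall_thickness = 10,
                            sprouts = list(), mscs = list(),
                            psf_sigma = 1, gaussian_sd = 0.02,
                            poisson_scale = 200, seed = 1) {
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  stopifnot(vessel_radius > 0, wall_thickness > 0, all(domain_size > 0))
  structure(list(vessel_radius = vessel_radius, domain_size = domain_size,
                 voxel_size = voxel_size, wall_thickness = wall_thickness,
                 sprouts = sprouts, mscs = mscs, psf_sigma = psf_sigma,
                 gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec_3d")
}

# voxel-centre coordinates along one axis
.vox_centers <- function(n, d) (seq_len(n) - 0.5) * d

# orthonormal frame whose first column is u
.frame_from_axis <- function(u) {
  u <- u / sqrt(sum(u^2))
  helper <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- helper - sum(helper * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  cbind(u, v, w)
}

# sprout base point and unit direction in world coordinates
.sprout_geometry <- function(sp, spec) {
  cy <- spec$domain_size[2] / 2
  cz <- spec$domain_size[3] / 2
  a <- sp$base_angle * pi / 180
  dirv <- c(0, sin(a), cos(a))      # polar angle in the y-z plane around x
  dirv[abs(dirv) < 1e-12] <- 0
  base <- c(sp$base_x, cy + spec$vessel_radius * dirv[2],
            cz + spec$vessel_radius * dirv[3])
  list(base = base, dir = dirv / sqrt(sum(dirv^2)))
}

.sprout_radius_at <- function(sp, s) {
  sp$base_radius + (sp$tip_radius - sp$base_radius) * s / sp$length +
    sp$roughness_amplitude * sin(2 * pi * s / sp$roughness_wavelength)
}

# bounding box (index ranges) around a segment with radial margin
.bbox_ranges <- function(p0, p1, margin, xs, ys, zs) {
  lo <- pmin(p0, p1) - margin
  hi <- pmax(p0, p1) + margin
  list(x = which(xs >= lo[1] & xs <= hi[1]),
       y = which(ys >= lo[2] & ys <= hi[2]),
       z = which(zs >= lo[3] & zs <= hi[3]))
}

# membership arrays for one sprout, restricted to its bounding box
.sprout_membership <- function(sp, spec, xs, ys, zs) {
  g <- .sprout_geometry(sp, spec)
  mrg <- max(sp$base_radius, sp$tip_radius) + sp$roughness_amplitude +
    spec$wall_thickness + 2 * max(spec$voxel_size)
  bb <- .bbox_ranges(g$base - spec$wall_thickness * g$dir,
                     g$base + sp$length * g$dir, mrg, xs, ys, zs)
  nx <- length(bb$x); ny <- length(bb$y); nz <- length(bb$z)
  px <- array(xs[bb$x], c(nx, ny, nz))
  py <- array(rep(ys[bb$y], each = nx), c(nx, ny, nz))
  pz <- array(rep(zs[bb$z], each = nx * ny), c(nx, ny, nz))
  rx <- px - g$base[1]; ry <- py - g$base[2]; rz <- pz - g$base[3]
  s <- rx * g$dir[1] + ry * g$dir[2] + rz * g$dir[3]
  qx <- rx - s * g$dir[1]; qy <- ry - s * g$dir[2]; qz <- rz - s * g$dir[3]
  rad2 <- qx^2 + qy^2 + qz^2
  rs <- .sprout_radius_at(sp, pmin(pmax(s, 0), sp$length))
  inside <- s >= -spec$wall_thickness & s <= sp$length & rad2 <= rs^2
  list(inside = inside, rad2 = rad2, rs = rs, s = s, bbox = bb)
}

.msc_resolved_center <- function(m, spec, i) {
  if (!is.null(m$center)) return(m)
  cy <- spec$domain_size[2] / 2; cz <- spec$domain_size[3] / 2
  if (identical(m$attached_to, "parent")) {
    a <- m$attach_angle * pi / 180
    m$center <- c(m$attach_s * spec$domain_size[1],
                  cy + spec$vessel_radius * sin(a),
                  cz + spec$vessel_radius * cos(a))
  } else if (grepl("^sprout_", m$attached_to)) {
    k <- as.integer(sub("sprout_", "", m$attached_to))
    if (k < 1 || k > length(spec$sprouts))
      stop("msc ", i, " attached to unknown sprout_", k)
    sp <- spec$sprouts[[k]]
    g <- .sprout_geometry(sp, spec)
    s <- m$attach_s * sp$length
    rs <- .sprout_radius_at(sp, s)
    fr <- .frame_from_axis(g$dir)
    a <- m$attach_angle * pi / 180
    radial <- fr[, 2] * cos(a) + fr[, 3] * sin(a)
    m$center <- g$base + s * g$dir + rs * radial
    m$axis <- g$dir  # attached cells elongate along the sprout
  } else {
    stop("msc ", i, " has no center and attached_to = 'none'")
  }
  m
}

.ellipsoid_membership <- function(m, xs, ys, zs) {
  fr <- .frame_from_axis(m$axis)
  bb <- .bbox_ranges(m$center, m$center, max(m$semi_axes) + 1, xs, ys, zs)
  nx <- length(bb$x); ny <- length(bb$y); nz <- length(bb$z)
  px <- array(xs[bb$x], c(nx, ny, nz)) - m$center[1]
  py <- array(rep(ys[bb$y], each = nx), c(nx, ny, nz)) - m$center[2]
  pz <- array(rep(zs[bb$z], each = nx * ny), c(nx, ny, nz)) - m$center[3]
  u <- (px * fr[1, 1] + py * fr[2, 1] + pz * fr[3, 1]) / m$semi_axes[1]
  v <- (px * fr[1, 2] + py * fr[2, 2] + pz * fr[3, 2]) / m$semi_axes[2]
  w <- (px * fr[1, 3] + py * fr[2, 3] + pz * fr[3, 3]) / m$semi_axes[3]
  list(inside = u^2 + v^2 + w^2 <= 1, bbox = bb)
}

# write values into the full array at a bounding-box membership
.apply_bbox <- function(arr, bb, member, value) {
  sub <- arr[bb$x, bb$y, bb$z]
  sub[member] <- value
  arr[bb$x, bb$y, bb$z] <- sub
  arr
}

.apply_bbox_if <- function(arr, bb, member, cond_sub, value) {
  sub <- arr[bb$x, bb$y, bb$z]
  sub[member & cond_sub] <- value
  arr[bb$x, bb$y, bb$z] <- sub
  arr
}

#' Rasterize an analytic solid primitive into a binary mask
#'
#' Convenience for oracle tests: spheres, solid cylinders along x, and
#' axis-aligned boxes at known position, with the voxel-centre convention
#' used everywhere in the package.
#'
#' @param type `"sphere"`, `"cylinder"` (axis +x) or `"box"`
#' @param radius sphere/cylinder radius (um)
#' @param length cylinder length (um)
#' @param side box edge lengths (um), length-3
#' @param domain_size,voxel_size domain extent and voxel pitch (um)
#' @param center primitive centre; default domain centre
#' @return logical array with attributes `voxel_size` and `center`
#' @export
primitive_mask <- function(type = c("sphere", "cylinder", "box"),
                           radius = 25, length = 100, side = c(10, 10, 10),
                           domain_size = NULL, voxel_size = c(1, 1, 1),
                           center = NULL) {
  type <- match.arg(type)
  if (is.null(domain_size)) {
    pad <- 12 * max(voxel_size)
    domain_size <- switch(type,
      sphere = rep(2 * radius + 2 * pad, 3),
      cylinder = c(length + 2 * pad, rep(2 * radius + 2 * pad, 2)),
      box = side + 2 * pad)
  }
  dims <- pmax(2L, as.integer(round(domain_size / voxel_size)))
  xs <- .vox_centers(dims[1], voxel_size[1])
  ys <- .vox_centers(dims[2], voxel_size[2])
  zs <- .vox_centers(dims[3], voxel_size[3])
  if (is.null(center)) center <- domain_size / 2
  mask <- switch(type,
    sphere = {
      d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
                  (zs - center[3])^2, "+")
      d2 <= radius^2
    },
    cylinder = {
      r2 <- outer((ys - center[2])^2, (zs - center[3])^2, "+")
      inx <- abs(xs - center[1]) <= length / 2
      arr <- array(FALSE, dims)
      arr[inx, , ] <- rep(r2 <= radius^2, each = sum(inx))
      arr
    },
    box = {
      ix <- abs(xs - center[1]) <= side[1] / 2
      iy <- abs(ys - center[2]) <= side[2] / 2
      iz <- abs(zs - center[3]) <= side[3] / 2
      outer(outer(ix, iy, "&"), iz, "&")
    })
  mask <- array(mask, dims)
  attr(mask, "voxel_size") <- voxel_size
  attr(mask, "center") <- center
  mask
}

#' Analytic signed mean curvature of simple primitives
#'
#' Oracle values under the sign convention used by the package: a convex
#' surface (bulging outward, like a solid sphere seen from outside) has
#' negative mean curvature, a concave one positive, a plane zero.
#'
#' @param primitive `"plane"`, `"sphere"` or `"cylinder"` (lateral surface
#'   of a solid cylinder)
#' @param r radius (um); ignored for `"plane"`
#' @return mean curvature in 1/um
#' @export
analytic_mean_curvature <- function(primitive = c("plane", "sphere", "cylinder"),
                                    r = NULL) {
  primitive <- match.arg(primitive)
  if (primitive == "plane") return(0)
  if (is.null(r) || r <= 0) stop("r must be positive for curved primitives")
  switch(primitive, sphere = -1 / r, cylinder = -1 / (2 * r))
}

#' Generate a 3D vessel phantom with ground truth
#'
#' Rasterizes the parent vessel (10 um endothelial shell), sprouts, MSC
#' ellipsoids and nuclei into a three-channel volume (red = endothelium,
#' green = MSC, blue = nuclei), applies Gaussian PSF blur and
#' Poisson-then-Gaussian noise, and returns per-voxel ground-truth labels
#' plus analytic reference quantities.
#'
#' Label codes: 0 background, 1 lumen, 2 parent wall, `10 + i` sprout i,
#' `100 + j` MSC j (labels partition the domain; vessel takes precedence
#' over sprouts, cells are labelled only outside the vessel/sprout solid).
#'
#' @param spec a [phantom_spec_3d()]
#' @return list with elements `volume` (class `volume_stack`: channels
#'   `red`, `green`, `blue`, `voxel_size`) and `truth` (labels, MSC table,
#'   per-sprout axial extent and true surface-coverage fractions, vessel
#'   geometry, analytic curvatures)
#' @export
make_vessel_phantom_3d <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec_3d"))
  dims <- as.integer(round(spec$domain_size / spec$voxel_size))
  if (any(dims < 4)) stop("domain too small for the voxel size")
  xs <- .vox_centers(dims[1], spec$voxel_size[1])
  ys <- .vox_centers(dims[2], spec$voxel_size[2])
  zs <- .vox_centers(dims[3], spec$voxel_size[3])
  cy <- spec$domain_size[2] / 2; cz <- spec$domain_size[3] / 2
  R <- spec$vessel_radius; wt <- spec$wall_thickness

  # sprouts must stay inside the domain
  for (i in seq_along(spec$sprouts)) {
    sp <- spec$sprouts[[i]]
    g <- .sprout_geometry(sp, spec)
    tip <- g$base + sp$length * g$dir
    margin <- sp$tip_radius
    if (any(tip - margin < 0) || any(tip + margin > spec$domain_size))
      stop("sprout ", i, " extends outside the domain")
  }

  r2yz <- outer((ys - cy)^2, (zs - cz)^2, "+")  # ny x nz
  vessel_solid <- array(rep(r2yz <= R^2, each = dims[1]), dims)
  lumen <- array(rep(r2yz <= (R - wt)^2, each = dims[1]), dims)
  wall <- vessel_solid & !lumen

  labels <- array(0L, dims)
  labels[lumen] <- 1L
  labels[wall] <- 2L

  red <- array(0, dims)
  red[wall] <- 1

  sprout_extent <- list()
  for (i in seq_along(spec$sprouts)) {
    sp <- spec$sprouts[[i]]
    mem <- .sprout_membership(sp, spec, xs, ys, zs)
    bb <- mem$bbox
    vs_sub <- vessel_solid[bb$x, bb$y, bb$z]
    solid <- mem$inside & !vs_sub
    # endothelial shell: lateral wall plus a capped tip (sealed lumen)
    shell <- solid & (mem$rad2 > pmax(0, mem$rs - wt)^2 |
                        mem$s > sp$length - wt)
    red <- .apply_bbox(red, bb, shell, 1)
    lab_sub <- labels[bb$x, bb$y, bb$z]
    lab_sub[solid & lab_sub == 0L] <- 10L + i
    labels[bb$x, bb$y, bb$z] <- lab_sub
    svals <- mem$s[solid]
    sprout_extent[[i]] <- if (length(svals)) range(svals) else c(NA, NA)
  }

  green <- array(0, dims)
  blue <- array(0, dims)
  mscs <- lapply(seq_along(spec$mscs), function(j)
    .msc_resolved_center(spec$mscs[[j]], spec, j))
  for (j in seq_along(mscs)) {
    m <- mscs[[j]]
    em <- .ellipsoid_membership(m, xs, ys, zs)
    green <- .apply_bbox(green, em$bbox, em$inside, 1)
    lab_sub <- labels[em$bbox$x, em$bbox$y, em$bbox$z]
    lab_sub[em$inside & lab_sub == 0L] <- 100L + j
    labels[em$bbox$x, em$bbox$y, em$bbox$z] <- lab_sub
    nuc <- .ellipsoid_membership(
      msc_spec(center = m$center, semi_axes = rep(4, 3)), xs, ys, zs)
    blue <- .apply_bbox(blue, nuc$bbox, nuc$inside, 1)
  }

  clean_red <- red
  channels <- list(red = red, green = green, blue = blue)
  set.seed(spec$seed)
  sig_vox <- spec$psf_sigma / spec$voxel_size
  for (ch in names(channels)) {
    v <- channels[[ch]]
    if (spec$psf_sigma > 0)
      v <- smooth_gaussian_3d_cpp(v, dims, sig_vox)
    if (spec$poisson_scale > 0)
      v <- array(rpois(length(v), pmax(v, 0) * spec$poisson_scale) /
                   spec$poisson_scale, dims)
    if (spec$gaussian_sd > 0)
      v <- v + array(rnorm(length(v), 0, spec$gaussian_sd), dims)
    channels[[ch]] <- v
  }

  coverage <- vapply(seq_along(spec$sprouts), function(i)
    .sprout_coverage_truth(spec$sprouts[[i]], spec, mscs), numeric(1))

  msc_table <- if (length(mscs)) {
    do.call(rbind, lapply(seq_along(mscs), function(j) {
      m <- mscs[[j]]
      data.frame(id = j, cx = m$center[1], cy = m$center[2], cz = m$center[3],
                 a = m$semi_axes[1], b = m$semi_axes[2], c = m$semi_axes[3],
                 attached_to = m$attached_to)
    }))
  } else data.frame()

  volume <- structure(list(red = channels$red, green = channels$green,
                           blue = channels$blue,
                           voxel_size = spec$voxel_size),
                      class = "volume_stack")
  truth <- list(
    labels = labels,
    clean_red = clean_red,
    msc = msc_table,
    sprout_extent = sprout_extent,
    sprout_coverage = coverage,
    vessel = list(radius = R, wall_thickness = wt, center_yz = c(cy, cz),
                  axis = c(1, 0, 0)),
    curvature = list(parent_wall = analytic_mean_curvature("cylinder", R)))
  list(volume = volume, truth = truth)
}

# true fraction of the sprout surface inside any MSC ellipsoid, by
# dense parametric sampling with exact area elements (lateral wall plus
# tip cap); erosion_um drops samples closer than that distance to the
# parent cylinder, matching an erosion-defined analysis scope
.sprout_surface_truth_one <- function(sp, spec, mscs, erosion_um = 0,
                                      n_s = 400, n_theta = 180) {
  g <- .sprout_geometry(sp, spec)
  fr <- .frame_from_axis(g$dir)
  s <- seq(0, sp$length, length.out = n_s)
  ds <- diff(s[1:2])
  dtheta <- 2 * pi / n_theta
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-1]
  rs <- .sprout_radius_at(sp, s)
  drds <- (sp$tip_radius - sp$base_radius) / sp$length +
    sp$roughness_amplitude * (2 * pi / sp$roughness_wavelength) *
      cos(2 * pi * s / sp$roughness_wavelength)
  wgt <- rs * sqrt(1 + drds^2) * ds * dtheta  # dA per lateral sample
  pts_s <- rep(s, times = n_theta)
  pts_t <- rep(theta, each = n_s)
  pts_w <- rep(wgt, times = n_theta)
  radial <- outer(fr[, 2], cos(pts_t)) + outer(fr[, 3], sin(pts_t))  # 3 x N
  P <- t(g$base + outer(g$dir, pts_s) + radial *
           rep(rep(rs, times = n_theta), each = 1)[col(radial)])
  # tip cap disk at s = length
  r_tip <- .sprout_radius_at(sp, sp$length)
  rho <- seq(r_tip / 80, r_tip, length.out = 40)
  drho <- diff(rho[1:2])
  cap_t <- rep(theta, each = length(rho))
  cap_rho <- rep(rho, times = n_theta)
  cap_radial <- outer(fr[, 2], cos(cap_t)) + outer(fr[, 3], sin(cap_t))
  P_cap <- t(g$base + outer(g$dir, rep(sp$length, length(cap_t))) +
               cap_radial * cap_rho[col(cap_radial)])
  P <- rbind(P, P_cap)
  pts_w <- c(pts_w, cap_rho * drho * dtheta)   # dA per cap sample
  if (erosion_um > 0) {
    cy <- spec$domain_size[2] / 2
    cz <- spec$domain_size[3] / 2
    dist_parent <- sqrt((P[, 2] - cy)^2 + (P[, 3] - cz)^2) -
      spec$vessel_radius
    keep <- dist_parent > erosion_um
    P <- P[keep, , drop = FALSE]
    pts_w <- pts_w[keep]
  }
  covered <- rep(FALSE, nrow(P))
  for (m in mscs) {
    frm <- .frame_from_axis(m$axis)
    q <- sweep(P, 2, m$center) %*% frm
    q <- sweep(q, 2, m$semi_axes, "/")
    covered <- covered | rowSums(q^2) <= 1
  }
  list(area = sum(pts_w), covered_fraction = sum(pts_w[covered]) / sum(pts_w))
}

.sprout_coverage_truth <- function(sp, spec, mscs) {
  if (!length(mscs)) return(0)
  .sprout_surface_truth_one(sp, spec, mscs)$covered_fraction
}

#' Analytic ground truth for sprout surface area and MSC coverage
#'
#' Dense parametric sampling of each sprout surface (lateral wall with
#' its exact area element, plus the tip cap). `erosion_um` drops samples
#' within that Euclidean distance of the parent cylinder, matching the
#' erosion-defined parent/sprout analysis scope (e.g. 10 voxels).
#'
#' @param spec a [phantom_spec_3d()]
#' @param erosion_um scope cut: minimum distance to the parent vessel
#'   surface (um); 0 keeps the whole sprout surface
#' @return data.frame per sprout: `sprout`, `area_um2`,
#'   `covered_fraction`
#' @export
sprout_surface_truth <- function(spec, erosion_um = 0) {
  stopifnot(inherits(spec, "phantom_spec_3d"))
  mscs <- lapply(seq_along(spec$mscs), function(j)
    .msc_resolved_center(spec$mscs[[j]], spec, j))
  rows <- lapply(seq_along(spec$sprouts), function(i) {
    tr <- .sprout_surface_truth_one(spec$sprouts[[i]], spec, mscs,
                                    erosion_um)
    data.frame(sprout = i, area_um2 = tr$area,
               covered_fraction = tr$covered_fraction)
  })
  do.call(rbind, rows)
}
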