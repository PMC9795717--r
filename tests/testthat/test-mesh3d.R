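# 3D preprocessing, surface reconstruction and the two vertex-tagging
# segmentations.

test_that("binarization recovers the phantom shell and removes salt noise", {
  ph <- fx_phantom_smooth()
  mask <- fx_pipeline_smooth()$mask
  truth_fg <- ph$truth$clean_red > 0
  jac <- sum(mask & truth_fg) / sum(mask | truth_fg)
  expect_gte(jac, 0.95)

  # single salt voxel is removed by the median filter
  v <- array(0, c(9, 9, 9)); v[5, 5, 5] <- 1
  att <- function(a) { attr(a, "voxel_size") <- c(1, 1, 1); a }
  filtered <- median_filter_3d_cpp(att(v), c(9L, 9L, 9L), 1L)
  expect_true(all(filtered == 0))

  # radius 0 means thresholding only
  vol <- att(array(runif(27), c(3, 3, 3)))
  m0 <- preprocess_volume(vol, median_radius = 0, threshold = "fixed",
                          threshold_value = 0.5)
  expect_identical(as.logical(m0), as.logical(vol > 0.5))
  expect_error(preprocess_volume(att(array(1, c(3, 3, 3))),
                                 median_radius = 0, threshold = "fixed",
                                 threshold_value = 2),
               "all-background")
})

test_that("largest_component keeps the vessel and drops debris", {
  a <- array(FALSE, c(30, 20, 20))
  a[2:21, 5:14, 5:14] <- TRUE        # 2000-voxel block
  a[25:26, 2:4, 2:4] <- TRUE         # 18-voxel debris
  attr(a, "voxel_size") <- c(1, 1, 1)
  keep <- largest_component(a)
  expect_equal(sum(keep), 2000)
  expect_identical(largest_component(keep), keep)
  empty <- array(FALSE, c(3, 3, 3)); attr(empty, "voxel_size") <- c(1, 1, 1)
  expect_error(largest_component(empty), "empty")
})

test_that("hole filling closes the lumen but respects open vessel ends", {
  ph <- make_vessel_phantom_3d(phantom_spec_3d(
    domain_size = c(100, 300, 300), voxel_size = c(2, 2, 2),
    psf_sigma = 0, gaussian_sd = 0, poisson_scale = 0))
  shell <- ph$volume$red > 0.5
  attr(shell, "voxel_size") <- c(2, 2, 2)
  filled <- fill_mask_holes(shell, exclude_axes = 1)
  expect_true(all(filled[ph$truth$labels == 1L]))   # lumen filled
  plain <- fill_mask_holes(shell)                   # open ends: no fill
  expect_false(any(plain[ph$truth$labels == 1L]))
})

test_that("meshing a cube reproduces its area and volume", {
  mask <- primitive_mask("box", side = c(10, 10, 10), voxel_size = c(1, 1, 1))
  mesh <- mesh_from_mask(mask, smooth_sigma = 0)
  expect_lt(abs(surface_area(mesh) / 600 - 1), 0.05)
  expect_lt(abs(enclosed_volume(mesh) / 1000 - 1), 0.03)

  empty <- array(FALSE, c(4, 4, 4)); attr(empty, "voxel_size") <- c(1, 1, 1)
  expect_error(mesh_from_mask(empty), "empty")
})

test_that("meshes from interior masks are watertight with outward winding", {
  mesh <- fx_sphere_mesh()
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
  # signed volume positive iff faces are counter-clockwise from outside
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], ]; b <- V[F[, 2], ]; cc <- V[F[, 3], ]
  vol6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  expect_gt(sum(vol6), 0)
})

test_that("meshing error decreases when halving the voxel size", {
  vol_err <- vapply(c(2, 1), function(d) {
    mask <- primitive_mask("sphere", radius = 20, voxel_size = rep(d, 3))
    abs(enclosed_volume(mesh_from_mask(mask, smooth_sigma = 1)) /
          (4 / 3 * pi * 20^3) - 1)
  }, numeric(1))
  expect_lt(vol_err[2], vol_err[1])
})

test_that("parent region opening erases sprouts but keeps a plain cylinder", {
  pl <- fx_pipeline_smooth()
  ph <- fx_phantom_smooth()
  truth_parent <- ph$truth$labels %in% c(1L, 2L)
  agree <- sum(pl$parent & truth_parent) / sum(pl$parent | truth_parent)
  expect_gte(agree, 0.95)
  # sprout voxels excluded from the parent region
  sprout_vox <- ph$truth$labels >= 10L & ph$truth$labels < 100L
  expect_lt(mean(pl$parent[sprout_vox]), 0.05)

  # plain through-domain tube: parent region ~ whole mask (the ball
  # opening loses up to a voxel of radius to EDT quantization, a
  # ~2/r_vox volume ring at 2 um voxels)
  cyl <- fx_tube_mask()
  parent <- define_parent_region(cyl, nominal_radius = 100)
  expect_gt(sum(parent & cyl) / sum(cyl | parent), 0.9)
  expect_error(define_parent_region(cyl, nominal_radius = 0), "positive")
})

test_that("sprout-tagged fraction matches the analytic surface oracle", {
  # noise-free single-sprout phantom so the surface is geometrically exact
  vox <- 2.5
  spec <- phantom_spec_3d(
    domain_size = c(300, 560, 300), voxel_size = rep(vox, 3),
    sprouts = list(sprout_spec(base_x = 150, base_angle = 90, length = 150)),
    psf_sigma = 0, gaussian_sd = 0, poisson_scale = 0)
  ph <- make_vessel_phantom_3d(spec)
  mask <- preprocess_volume(ph$volume, "red", median_radius = 0,
                            threshold = "fixed", threshold_value = 0.5)
  filled <- fill_mask_holes(mask, exclude_axes = 1)
  parent <- define_parent_region(filled, nominal_radius = 100)
  mesh <- mesh_from_mask(filled, smooth_sigma = 1)
  erosion_px <- 10
  # border-padding vertices sit fractionally outside the voxel grid and
  # are clamped (expected for a through-domain vessel)
  mesh <- suppressWarnings(
    tag_parent_vs_sprout(mesh, parent, erosion_px = erosion_px))
  frac_meas <- surface_area(mesh, "sprout") / surface_area(mesh)

  # parametric oracle: tapered-cone lateral area above the erosion band,
  # plus the tip cap, over the total solid surface (tube + caps + sprout)
  sp <- spec$sprouts[[1]]
  r_at <- function(s) sp$base_radius +
    (sp$tip_radius - sp$base_radius) * s / sp$length
  lat_between <- function(s0, s1) {
    s <- seq(s0, s1, length.out = 1000)
    drds <- (sp$tip_radius - sp$base_radius) / sp$length
    2 * pi * mean(r_at(s) * sqrt(1 + drds^2)) * (s1 - s0)
  }
  # the erosion band is measured from the parent solid, whose convex
  # wall falls away under the sprout: a lateral point at height s and
  # radial offset r(s) is s + sagitta(r(s)) from the wall
  sagitta <- function(rho) 100 - sqrt(100^2 - rho^2)
  s_cut <- erosion_px * vox
  for (it in 1:20) s_cut <- erosion_px * vox - sagitta(r_at(s_cut))
  sprout_true <- lat_between(s_cut, sp$length) + pi * r_at(sp$length)^2
  total_true <- 2 * pi * 100 * 300 - pi * sp$base_radius^2 +
    2 * pi * 100^2 + lat_between(0, sp$length) + pi * r_at(sp$length)^2
  frac_true <- sprout_true / total_true
  expect_lt(abs(frac_meas - frac_true) / frac_true, 0.1)
})

test_that("parent/sprout tagging behaves under erosion and re-application", {
  pl <- fx_pipeline_smooth()
  mesh <- pl$mesh
  expect_true(all(mesh$region %in% c("parent", "sprout")))

  # plain through-domain tube gets no sprout tags at default erosion
  cyl <- fx_tube_mask()
  parent <- define_parent_region(cyl, nominal_radius = 100)
  cmesh <- suppressWarnings(mesh_from_mask(cyl, smooth_sigma = 1))
  cmesh <- suppressWarnings(tag_parent_vs_sprout(cmesh, parent,
                                                 erosion_px = 10))
  expect_equal(sum(cmesh$region == "sprout"), 0)

  # erosion 0 strictly grows the sprout set
  mesh0 <- tag_parent_vs_sprout(mesh, pl$parent, erosion_px = 0)
  expect_gt(sum(mesh0$region == "sprout"), sum(mesh$region == "sprout"))

  # re-tagging with identical inputs changes nothing
  again <- tag_parent_vs_sprout(mesh, pl$parent, erosion_px = 10)
  expect_identical(again$region, mesh$region)
})

test_that("coverage tags respond to the green mask and match contact patches", {
  pl <- fx_pipeline_smooth()
  mesh <- pl$mesh
  d <- dim(pl$filled)
  none <- array(FALSE, d); attr(none, "voxel_size") <- rep(2.5, 3)
  all_g <- array(TRUE, d); attr(all_g, "voxel_size") <- rep(2.5, 3)
  m0 <- tag_msc_coverage(mesh, none)
  expect_equal(sum(m0$coverage == "covered"), 0)
  m1 <- tag_msc_coverage(mesh, all_g)
  expect_equal(mean(m1$coverage == "covered"), 1)

  # covered vertex patches overlap the ground-truth contact geometry:
  # vertices within any attached MSC ellipsoid (evaluated analytically)
  ph <- fx_phantom_smooth()
  spec <- fx_spec3d(0)
  mscs <- lapply(seq_along(spec$mscs), function(j)
    angiocross:::.msc_resolved_center(spec$mscs[[j]], spec, j))
  inside_any <- rep(FALSE, nrow(mesh$vertices))
  for (m in mscs) {
    fr <- angiocross:::.frame_from_axis(m$axis)
    q <- sweep(mesh$vertices, 2, m$center) %*% fr
    q <- sweep(q, 2, m$semi_axes, "/")
    inside_any <- inside_any | rowSums(q^2) <= 1
  }
  meas <- mesh$coverage == "covered"
  jac <- sum(meas & inside_any) / sum(meas | inside_any)
  expect_gte(jac, 0.8)
})

test_that("anisotropic stacks resample to isotropic voxels faithfully", {
  ph <- make_vessel_phantom_3d(phantom_spec_3d(
    domain_size = c(60, 300, 300), voxel_size = c(2, 2, 6),
    psf_sigma = 0, gaussian_sd = 0, poisson_scale = 0))
  arr <- ph$volume$red
  attr(arr, "voxel_size") <- c(2, 2, 6)
  iso <- resample_isotropic(arr)
  expect_equal(attr(iso, "voxel_size"), c(2, 2, 2))
  expect_equal(dim(iso)[3], 150)
  # resampled shell stays close to the analytically rasterized one
  direct <- make_vessel_phantom_3d(phantom_spec_3d(
    domain_size = c(60, 300, 300), voxel_size = c(2, 2, 2),
    psf_sigma = 0, gaussian_sd = 0, poisson_scale = 0))$volume$red
  agree <- mean((iso > 0.5) == (direct > 0.5))
  expect_gt(agree, 0.97)
})
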