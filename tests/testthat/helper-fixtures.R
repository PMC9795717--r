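# Shared fixtures, built once per test run and cached. Everything is
# generated in code; sizes are chosen so the whole suite stays within a
# few minutes on one CPU.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# icosphere r = 25 um rasterized at 1 um voxels, meshed for curvature
fx_sphere_mesh <- function() fixture("sphere_mesh", function() {
  mask <- primitive_mask("sphere", radius = 25, voxel_size = c(1, 1, 1))
  mesh_from_mask(mask, smooth_sigma = 1, fair_t = 10)
})

# solid cylinder r = 100, L = 100 um at 1 um voxels (curvature grade)
fx_cyl_mesh_faired <- function() fixture("cyl_mesh_faired", function() {
  mask <- primitive_mask("cylinder", radius = 100, length = 100,
                         voxel_size = c(1, 1, 1))
  mesh_from_mask(mask, smooth_sigma = 1, fair_t = 10)
})

# same cylinder, geometry-faithful meshing (no fairing)
fx_cyl_mesh_raw <- function() fixture("cyl_mesh_raw", function() {
  mask <- primitive_mask("cylinder", radius = 100, length = 100,
                         voxel_size = c(1, 1, 1))
  mesh_from_mask(mask, smooth_sigma = 1, fair_t = 0)
})

# noise-free 2D co-culture series (pipeline-recovery conditions)
fx_series_nf <- function() fixture("series_nf", function() {
  make_coculture_series_2d(
    phantom_spec_2d(seed = 7, gaussian_sd = 0, poisson_scale = 0))
})

# default noisy 2D series
fx_series <- function() fixture("series", function() {
  make_coculture_series_2d(phantom_spec_2d(seed = 3))
})

# 3D co-culture-like phantom (smooth sprouts + attached MSCs) and the
# monoculture-like rough variant; shared by segmentation/morphometry and
# the end-to-end contrast suite
fx_spec3d <- function(amp, seed = 11, mscs = TRUE) {
  phantom_spec_3d(
    domain_size = c(400, 560, 300), voxel_size = c(2.5, 2.5, 2.5),
    sprouts = list(
      sprout_spec(base_x = 150, base_angle = 90, length = 150,
                  roughness_amplitude = amp, roughness_wavelength = 30),
      sprout_spec(base_x = 280, base_angle = 270, length = 150,
                  roughness_amplitude = amp, roughness_wavelength = 30)),
    mscs = if (mscs) list(
      msc_spec(attached_to = "sprout_1", attach_s = 0.35, attach_angle = 0,
               semi_axes = c(35, 16, 16)),
      msc_spec(attached_to = "sprout_1", attach_s = 0.7, attach_angle = 180,
               semi_axes = c(35, 16, 16)),
      msc_spec(attached_to = "sprout_2", attach_s = 0.65, attach_angle = 90,
               semi_axes = c(35, 16, 16)),
      msc_spec(attached_to = "sprout_2", attach_s = 0.3, attach_angle = 270,
               semi_axes = c(35, 16, 16)),
      msc_spec(attached_to = "parent", attach_s = 0.15, attach_angle = 45,
               semi_axes = c(35, 16, 16))) else list(),
    seed = seed)
}

fx_phantom_smooth <- function() fixture("phantom_smooth", function() {
  make_vessel_phantom_3d(fx_spec3d(0))
})

fx_phantom_rough <- function() fixture("phantom_rough", function() {
  make_vessel_phantom_3d(fx_spec3d(8, seed = 12, mscs = FALSE))
})

# full 3D reconstruction pipeline on a phantom: masks, parent region,
# tagged + curvature mesh
fx_reconstruct <- function(ph, fair_t = 10) {
  mask <- largest_component(preprocess_volume(ph$volume, "red",
                                              median_radius = 1))
  filled <- fill_mask_holes(mask, exclude_axes = 1)
  parent <- define_parent_region(filled, nominal_radius = 100)
  mesh <- mesh_from_mask(filled, smooth_sigma = 1, fair_t = fair_t)
  mesh <- tag_parent_vs_sprout(mesh, parent, erosion_px = 10)
  if (max(ph$volume$green) > 0) {
    gmask <- preprocess_volume(ph$volume, "green", median_radius = 1)
    mesh <- tag_msc_coverage(mesh, gmask)
  }
  mesh <- mean_curvature(mesh)
  list(mask = mask, filled = filled, parent = parent, mesh = mesh)
}

fx_pipeline_smooth <- function() fixture("pipeline_smooth", function() {
  suppressWarnings(fx_reconstruct(fx_phantom_smooth()))
})

fx_pipeline_rough <- function() fixture("pipeline_rough", function() {
  suppressWarnings(fx_reconstruct(fx_phantom_rough()))
})

# match measured particles to ground-truth objects of one frame by
# nearest centroid; returns truth status / measured label pairs
match_particles <- function(classified, truth_frame, max_px = 6) {
  out <- lapply(seq_len(nrow(classified)), function(i) {
    d2 <- (truth_frame$cx_px - classified$cx[i])^2 +
      (truth_frame$cy_px - classified$cy[i])^2
    j <- which.min(d2)
    data.frame(true = as.character(truth_frame$status[j]),
               measured = as.character(classified$label[i]),
               match_px = sqrt(d2[j]),
               true_id = truth_frame$id[j],
               true_dist_um = truth_frame$dist_edge_um[j],
               tilt_true = truth_frame$tilt_deg[j],
               tilt_measured = classified$tilt_deg[i])
  })
  do.call(rbind, out)
}

# adjusted Rand index between two labelled partitions
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
.mwu_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  u_obs <- r_obs - n1 * (n1 + 1) / 2
  u_all <- apply(idx, 2, function(ix) {
    sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# brute-force KS D: sweep the ECDF difference over all pooled points
.ks_d_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}


# rows whose ground-truth object is well clear of both margin lines; the
# margin-defining day-1 object sits exactly on the inner line, so its
# classification under sub-pixel measurement noise is a coin toss by
# construction and is not a meaningful scoring target
unambiguous <- function(matched, margin_px, pixel_size = 0.89,
                        clearance_px = 3) {
  band_um <- margin_px * pixel_size
  d <- matched$true_dist_um
  pmin(abs(d - band_um), abs(d + band_um)) > clearance_px * pixel_size
}

# solid tube running through the whole domain along x (no end caps
# inside the stack), as the templated vessel does
fx_tube_mask <- function(radius = 100, voxel = 2) {
  primitive_mask("cylinder", radius = radius, length = 1000,
                 domain_size = c(300, 2 * radius + 48, 2 * radius + 48),
                 voxel_size = rep(voxel, 3))
}
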