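# 2D analysis: kernel-window density maps and correlation, vessel-edge
# extraction, particle/orientation analysis, margin derivation and
# neighbor/distant classification.

test_that("kernel density maps sum non-overlapping windows", {
  ones <- list(red = matrix(1, 100, 100), green = matrix(1, 100, 100))
  m <- kernel_density_maps(ones, 50)
  expect_equal(dim(m$red$grid), c(2, 2))
  expect_true(all(m$red$grid == 2500))

  # window 1 is the identity
  img <- list(red = matrix(runif(60), 6, 10), green = matrix(runif(60), 6, 10))
  m1 <- kernel_density_maps(img, 1)
  expect_equal(m1$red$grid, img$red)

  # 6x6 ramp, window 3: hand-summed oracle
  ramp <- matrix(1:36, 6, 6)
  oracle <- matrix(NA, 2, 2)
  for (i in 1:2) for (j in 1:2)
    oracle[i, j] <- sum(ramp[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)])
  m3 <- kernel_density_maps(list(red = ramp, green = ramp), 3)
  expect_equal(m3$red$grid, oracle)

  # trailing partial windows are discarded
  m2 <- kernel_density_maps(list(red = matrix(1, 7, 5),
                                 green = matrix(1, 7, 5)), 3)
  expect_equal(dim(m2$red$grid), c(2, 1))
  expect_error(kernel_density_maps(ones, 200), "larger")
})

test_that("density correlation matches the textbook Pearson formula", {
  dm <- function(v) structure(list(grid = matrix(v, 2, 2), window_px = 1),
                              class = "density_map")
  expect_equal(density_correlation(dm(1:4), dm(1:4))$r, 1)
  expect_equal(density_correlation(dm(1:4), dm(-(1:4) + 10))$r, -1)

  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 5)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  res <- density_correlation(dm(a), dm(b))
  expect_equal(res$r, hand)
  expect_true(res$correlated)   # hand value is ~0.98 > 0.6

  flat <- density_correlation(dm(rep(2, 4)), dm(1:4))
  expect_true(flat$zero_variance)
  expect_true(is.na(flat$r))
})

test_that("correlation is invariant to positive affine intensity rescaling", {
  ph <- fx_series()
  f <- ph$series$frames[[8]]
  m0 <- kernel_density_maps(f, 50)
  r0 <- density_correlation(m0$red, m0$green)$r
  f2 <- list(red = 3.7 * f$red + 11, green = 0.2 * f$green + 5)
  m2 <- kernel_density_maps(f2, 50)
  expect_equal(density_correlation(m2$red, m2$green)$r, r0, tolerance = 1e-12)
})

test_that("edge extraction recovers the noise-free vessel geometry", {
  ph <- fx_series_nf()
  v <- attr(ph$truth, "vessel")
  edges <- extract_vessel_edges(ph$series$frames[[1]]$red)
  sep <- edges$lower_y - edges$upper_y
  true_sep <- v$edge_lower_px - v$edge_upper_px
  expect_gte(mean(abs(sep - true_sep) <= 2), 0.98)
  expect_true(all(edges$upper_y <= edges$center_y),
              all(edges$lower_y >= edges$center_y))
  expect_error(extract_vessel_edges(matrix(0.5, 64, 64)), "constant")
})

test_that("an isolated wall bump appears in the edge trace at its height", {
  nx <- 400; ny <- 300
  red <- matrix(0, nx, ny)
  red[, 100:200] <- 0.9
  # bump of height 20 px on the upper wall, 60 px wide
  for (i in 150:210) {
    h <- round(20 * exp(-0.5 * ((i - 180) / 15)^2))
    if (h > 0) red[i, (100 - h):100] <- 0.9
  }
  edges <- extract_vessel_edges(red, params = list(smooth_window = 5))
  excursion <- (min(edges$upper_y[150:210]) -
                  median(edges$upper_y[c(1:100, 300:400)]))
  expect_lt(abs(-excursion - 20), 4)  # upper wall: bump means smaller y
})

test_that("particle detection fits ellipse orientation and folds angles", {
  img <- matrix(0, 300, 300)
  img <- angiocross:::.render_ellipse_2d(img, 150, 150, 40, 15, 30)
  p <- detect_msc_particles(img, params = list(tophat_radius = 0))
  expect_equal(nrow(p), 1)
  expect_lt(abs(p$tilt_deg - 30), 2)

  # 120 degrees in image coordinates folds to 60
  img2 <- angiocross:::.render_ellipse_2d(matrix(0, 300, 300),
                                          150, 150, 40, 15, 120)
  p2 <- detect_msc_particles(img2, params = list(tophat_radius = 0))
  expect_lt(abs(p2$tilt_deg - 60), 2)

  # rotating a fixture by theta and 180 - theta gives identical tilt
  img3 <- angiocross:::.render_ellipse_2d(matrix(0, 300, 300),
                                          150, 150, 40, 15, 180 - 30)
  p3 <- detect_msc_particles(img3, params = list(tophat_radius = 0))
  expect_equal(p3$tilt_deg, p$tilt_deg, tolerance = 0.5)
})

test_that("sub-threshold specks are dropped and empty results are valid", {
  img <- matrix(0, 200, 200)
  img <- angiocross:::.render_ellipse_2d(img, 50, 50, 20, 10, 0)
  img <- angiocross:::.render_ellipse_2d(img, 150, 150, 15, 8, 45)
  img[100, 100] <- 1  # 1-px speck, below min_area
  p <- detect_msc_particles(img, params = list(tophat_radius = 0,
                                               min_area = 20))
  expect_equal(nrow(p), 2)
  p0 <- detect_msc_particles(matrix(0, 50, 50),
                             params = list(tophat_radius = 0))
  expect_equal(nrow(p0), 0)
})

test_that("margins come from the deepest day-1 intraluminal centroid and freeze", {
  edges <- structure(list(upper_y = rep(100, 200), lower_y = rep(300, 200),
                          center_y = 200, valid = rep(TRUE, 200)),
                     class = "vessel_edges")
  parts <- data.frame(id = 1:3, cx = c(50, 80, 120),
                      cy = c(105, 112, 350),  # 5 and 12 px inside; 1 outside
                      area_px = 100, major_px = 30, minor_px = 10,
                      tilt_deg = 0)
  m <- derive_margins(parts, edges)
  expect_equal(m$d_in_px, 12)
  expect_equal(m$d_out_px, 12)
  expect_false(m$fallback_used)
  expect_equal(m$frozen_from_day, 1L)

  # no intraluminal objects: fallback = mean major axis, logged
  outside <- transform(parts, cy = c(350, 360, 370))
  expect_message(m2 <- derive_margins(outside, edges), "fallback")
  expect_true(m2$fallback_used)
  expect_equal(m2$d_in_px, 30)
})

test_that("classification labels follow the margin band with inclusive ties", {
  edges <- structure(list(upper_y = rep(100, 200), lower_y = rep(300, 200),
                          center_y = 200, valid = rep(TRUE, 200)),
                     class = "vessel_edges")
  m <- structure(list(d_in_px = 10, d_out_px = 10, frozen_from_day = 1L,
                      fallback_used = FALSE), class = "margin_spec")
  parts <- data.frame(id = 1:5, cx = rep(100, 5),
                      cy = c(90, 305, 311, 330, 285),
                      area_px = 100, major_px = 30, minor_px = 10,
                      tilt_deg = 0)
  # distances: 10 (on outer margin), 5, 11, 30, -15
  cl <- classify_particles(parts, edges, m)
  expect_equal(as.character(cl$label),
               c("neighbor", "neighbor", "distant", "distant",
                 "intraluminal"))
})

test_that("pipeline labels match phantom ground truth exactly", {
  ph <- fx_series_nf()
  edges1 <- extract_vessel_edges(ph$series$frames[[1]]$red)
  parts1 <- detect_msc_particles(ph$series$frames[[1]]$green)
  margins <- derive_margins(parts1, edges1)
  for (t in c(1, 6, 10)) {
    f <- ph$series$frames[[t]]
    edges <- extract_vessel_edges(f$red, center_y = edges1$center_y)
    cl <- classify_particles(detect_msc_particles(f$green), edges, margins)
    tr <- ph$truth[ph$truth$frame == t, ]
    matched <- match_particles(cl, tr)
    keep <- (matched$true %in% c("neighbor", "distant") |
               matched$measured %in% c("neighbor", "distant")) &
      unambiguous(matched, attr(ph$truth, "margin_px"))
    expect_identical(matched$true[keep], matched$measured[keep])
    # every unambiguous analysable ground-truth object is recovered
    amb_ids <- matched$true_id[!unambiguous(matched,
                                            attr(ph$truth, "margin_px"))]
    truth_analysable <- tr$status != "intraluminal" & !(tr$id %in% amb_ids)
    expect_equal(sum(matched$measured != "intraluminal" & keep),
                 sum(truth_analysable))
  }
})

test_that("orientation histograms conserve counts and separate locations", {
  parts <- data.frame(tilt_deg = c(0, 5, 12, 88, 90, 45),
                      label = factor(c("neighbor", "neighbor", "neighbor",
                                       "distant", "distant", "distant"),
                                     levels = c("neighbor", "distant",
                                                "intraluminal")))
  h <- orientation_distribution(parts, bin_width = 10)
  expect_equal(sum(h$count[h$label == "neighbor"]), 3)
  expect_equal(sum(h$count[h$label == "distant"]), 3)
  expect_equal(sum(h$count), 6)

  one_bin <- orientation_distribution(
    data.frame(tilt_deg = c(0, 0, 0),
               label = factor(rep("neighbor", 3),
                              levels = c("neighbor", "distant"))), 10)
  nb <- one_bin[one_bin$label == "neighbor", ]
  expect_equal(sum(nb$count > 0), 1)
  expect_equal(nb$count[1], 3)

  # aligned phantom: neighbors end up flatter than distant cells
  ph <- fx_series_nf()
  edges1 <- extract_vessel_edges(ph$series$frames[[1]]$red)
  parts1 <- detect_msc_particles(ph$series$frames[[1]]$green)
  margins <- derive_margins(parts1, edges1)
  f <- ph$series$frames[[10]]
  cl <- classify_particles(detect_msc_particles(f$green),
                           extract_vessel_edges(f$red,
                                                center_y = edges1$center_y),
                           margins)
  expect_lt(median(cl$tilt_deg[cl$label == "neighbor"]),
            median(cl$tilt_deg[cl$label == "distant"]))
})
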