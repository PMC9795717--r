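# Synthetic 2D co-culture time series (one frame per "day").
#
# The phantom reproduces the dynamics seen in chip co-cultures: MSCs
# scattered in the gel migrate toward the parent vessel at a constant
# rate, and once inside the neighbor band their tilt angle relaxes toward
# the vessel axis. Ground truth records centroids, angles, distances and
# neighbor/distant status at every frame.

#' Specify a 2D co-culture phantom
#'
#' The pixel size default (0.89 um/px) makes a 50-px kernel window equal
#' 44.5 um, the window geometry used for the colocalization analysis.
#'
#' @param frames number of frames (days); default 10
#' @param pixel_size um per pixel
#' @param image_size_px image size (nx, ny) in pixels; x is the vessel axis
#' @param vessel_radius parent vessel radius (um)
#' @param n_msc number of extraluminal MSCs
#' @param migration_rate um per frame toward the vessel edge
#' @param alignment_rate degrees per frame of tilt decay toward the vessel
#'   axis, applied while a cell is inside the neighbor band
#' @param msc_semi_axes MSC ellipse semi-axes (um)
#' @param margin_px ground-truth margin distance (px): the deepest
#'   day-1 intraluminal object sits this far inside the edge
#' @param n_intraluminal number of day-1 intraluminal seed objects (these
#'   calibrate the margin band and are therefore ground-truth neighbors:
#'   cells already in touch with the wall)
#' @param n_deep_intraluminal objects appearing deep inside the lumen from
#'   day 2 on; ground-truth status `"intraluminal"` (excluded from
#'   analysis)
#' @param n_wall_msc cells that adhere to and wrap around the tube wall;
#'   in the 2D projection they overlie the vessel band (driving the
#'   red-green colocalization seen in co-culture) and are ground-truth
#'   `"intraluminal"` (their projected centroids fall inside the edges,
#'   so the particle analysis excludes them). Their number grows linearly
#'   over the frames, mimicking progressive adhesion.
#' @param stop_distance standoff (um) at which migrating cells adhere to
#'   the wall
#' @param psf_sigma Gaussian blur sigma (um); 0 disables
#' @param gaussian_sd,poisson_scale imaging noise; 0 disables each
#' @param initial_distances optional numeric vector (length `n_msc`) of
#'   initial stand-off distances from the vessel edge (um), overriding the
#'   randomized placement (useful for closed-form kinematics checks)
#' @param allow_intraluminal permit intraluminal seeds (day-1 margin
#'   calibration objects); when `FALSE`, requesting them is an error
#' @param seed integer seed
#' @return a `phantom_spec_2d` list
#' @export
phantom_spec_2d <- function(frames = 10, pixel_size = 0.89,
                            image_size_px = c(800, 600),
                            vessel_radius = 100, n_msc = 20,
                            migration_rate = 10, alignment_rate = 10,
                            msc_semi_axes = c(20, 8), margin_px = 12,
                            n_intraluminal = 2, n_deep_intraluminal = 1, n_wall_msc = 60,
                            stop_distance = 2,
                            psf_sigma = 1.5, gaussian_sd = 0.02,
                            poisson_scale = 200, initial_distances = NULL,
                            allow_intraluminal = TRUE, seed = 1) {
  stopifnot(frames >= 1, n_msc >= 0, pixel_size > 0, vessel_radius > 0,
            migration_rate >= 0, alignment_rate >= 0, margin_px >= 0)
  if (!allow_intraluminal && n_intraluminal > 0)
    stop("intraluminal MSCs are disallowed by this spec")
  structure(list(frames = as.integer(frames), pixel_size = pixel_size,
                 image_size_px = as.integer(image_size_px),
                 vessel_radius = vessel_radius, n_msc = as.integer(n_msc),
                 migration_rate = migration_rate,
                 alignment_rate = alignment_rate,
                 msc_semi_axes = msc_semi_axes, margin_px = margin_px,
                 n_intraluminal = as.integer(n_intraluminal),
                 n_deep_intraluminal = as.integer(n_deep_intraluminal),
                 n_wall_msc = as.integer(n_wall_msc),
                 stop_distance = stop_distance, psf_sigma = psf_sigma,
                 gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
                 initial_distances = initial_distances,
                 seed = as.integer(seed)),
            class = "phantom_spec_2d")
}

# render one filled rotated ellipse into an [x, y] pixel matrix
.render_ellipse_2d <- function(img, cx_px, cy_px, a_px, b_px, angle_deg,
                               value = 1) {
  nx <- nrow(img); ny <- ncol(img)
  r <- ceiling(a_px) + 2
  x_lo <- max(1, floor(cx_px - r)); x_hi <- min(nx, ceiling(cx_px + r))
  y_lo <- max(1, floor(cy_px - r)); y_hi <- min(ny, ceiling(cy_px + r))
  if (x_lo > x_hi || y_lo > y_hi) return(img)
  xr <- x_lo:x_hi; yr <- y_lo:y_hi
  th <- angle_deg * pi / 180
  dx <- outer(xr - cx_px, rep(1, length(yr)))
  dy <- outer(rep(1, length(xr)), yr - cy_px)
  u <- (dx * cos(th) + dy * sin(th)) / a_px
  v <- (-dx * sin(th) + dy * cos(th)) / b_px
  sel <- u^2 + v^2 <= 1
  sub <- img[xr, yr]
  sub[sel] <- value
  img[xr, yr] <- sub
  img
}

#' Generate a 2D co-culture time series with ground truth
#'
#' Frame t (t = 1..frames, one per day) shows each MSC displaced by
#' `migration_rate * t` um from its initial position toward the nearest
#' vessel edge (clamping at `stop_distance` um outside the edge), with its
#' tilt angle reduced by `alignment_rate` degrees per frame spent inside
#' the neighbor band. Initial stand-off distances are laid out so that no
#' centroid ever falls within ~5 px of a margin line, keeping the
#' ground-truth labels unambiguous for pipeline scoring.
#'
#' @param spec a [phantom_spec_2d()]
#' @return list with `series` (class `image_series_2d`: `frames` = list of
#'   `list(red, green)` matrices `[x, y]`, `pixel_size`, `frame_days`) and
#'   `truth` (data.frame: frame, id, cx_px, cy_px, tilt_deg,
#'   dist_edge_um signed + outside the lumen, status, plus the margin
#'   band in `margin_px` and vessel geometry attributes)
#' @export
make_coculture_series_2d <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec_2d"))
  set.seed(spec$seed)
  nx <- spec$image_size_px[1]; ny <- spec$image_size_px[2]
  px <- spec$pixel_size
  cy_um <- ny / 2 * px
  R <- spec$vessel_radius
  d_band_um <- spec$margin_px * px   # neighbor band half-width (= d_in = d_out)

  # initial placement: jittered x grid, alternating sides; stand-off
  # distances quantized so per-frame distances avoid the margin line
  n <- spec$n_msc
  ids <- seq_len(n)
  xg <- seq(0.08, 0.92, length.out = max(n, 1)) * nx * px
  xg <- xg + runif(n, -0.005, 0.005) * nx * px
  side <- rep(c(1, -1), length.out = n)
  rate <- spec$migration_rate
  gap_px <- 6
  # distance above the outer margin, plus k full migration steps
  k_steps <- sample(0:min(3, max(1, spec$frames - 2)), n, replace = TRUE)
  extra <- runif(n, gap_px * px, max(rate - gap_px * px, gap_px * px + 1))
  dist0 <- d_band_um + k_steps * rate + extra
  # some cells never respond: they stay put (and distant) throughout
  far <- runif(n) < 0.35
  dist0[far] <- d_band_um + spec$frames * rate + runif(sum(far), 10, 40)
  # never place beyond the imaged gel region; stagger the caps so capped
  # cells do not end up at identical stand-off (merged blobs)
  max_dist <- (ny / 2) * px - spec$vessel_radius - 25
  over <- dist0 > max_dist
  dist0[over] <- max_dist - runif(sum(over), 0, 30)
  if (!is.null(spec$initial_distances)) {
    stopifnot(length(spec$initial_distances) == n)
    dist0 <- pmin(spec$initial_distances, max_dist)
    far[] <- FALSE
  }
  angle0 <- runif(n, 0, 90)

  # day-1 intraluminal calibration objects; the deepest sits margin_px
  # inside the edge and defines the ground-truth margin
  n_in <- spec$n_intraluminal
  intr <- if (n_in > 0) {
    depth_px <- c(spec$margin_px, runif(max(0, n_in - 1), 4, spec$margin_px - 2))
    data.frame(id = -seq_len(n_in),
               x_um = runif(n_in, 0.2, 0.8) * nx * px,
               side = rep(c(1, -1), length.out = n_in),
               depth_um = depth_px * px)
  } else NULL

  # keep arriving cells clear of the intraluminal seeds so green blobs
  # never merge across the edge (would break particle separation)
  if (!is.null(intr) && n > 0) {
    for (q in seq_len(nrow(intr))) {
      clash <- abs(xg - intr$x_um[q]) < 70 * px
      far[clash] <- TRUE
      dist0[clash] <- pmax(dist0[clash], 100 + runif(sum(clash), 0, 30))
    }
  }

  # wall-adhered (wrapping) cells: projected positions inside the band
  n_wall <- spec$n_wall_msc
  wall <- if (n_wall > 0) data.frame(
    id = 1000 + seq_len(n_wall),
    x_um = runif(n_wall, 0.05, 0.95) * nx * px,
    y_off = runif(n_wall, -(R - 25), R - 25),
    angle = runif(n_wall, 0, 30),
    appears = if (spec$frames >= 2)
      sort(rep(seq(2, spec$frames), length.out = n_wall)) else
      rep(1L, n_wall)) else NULL

  frames <- vector("list", spec$frames)
  truth <- vector("list", spec$frames)

  red0 <- matrix(0, nx, ny)
  yc_um <- (seq_len(ny) - 0.5) * px
  band <- abs(yc_um - cy_um) <= R
  red0[, band] <- 0.9

  for (t in seq_len(spec$frames)) {
    moved <- ifelse(far, 0, pmin(rate * t, pmax(dist0 - spec$stop_distance, 0)))
    dist_t <- dist0 - moved
    in_band_frames <- pmax(0, t - ceiling((dist0 - d_band_um) / max(rate, 1e-9)))
    angle_t <- pmax(0, angle0 - spec$alignment_rate * in_band_frames)
    status <- ifelse(dist_t > d_band_um, "distant", "neighbor")

    green <- matrix(0, nx, ny)
    rows <- list()
    for (i in seq_len(n)) {
      y_um <- cy_um + side[i] * (R + dist_t[i])
      green <- .render_ellipse_2d(green, xg[i] / px + 0.5, y_um / px + 0.5,
                                  spec$msc_semi_axes[1] / px,
                                  spec$msc_semi_axes[2] / px,
                                  side[i] * angle_t[i])
      rows[[length(rows) + 1]] <- data.frame(
        frame = t, id = i, cx_px = xg[i] / px, cy_px = y_um / px,
        tilt_deg = angle_t[i], dist_edge_um = dist_t[i], status = status[i])
    }
    if (!is.null(intr)) {
      for (q in seq_len(nrow(intr))) {
        y_um <- cy_um + intr$side[q] * (R - intr$depth_um[q])
        green <- .render_ellipse_2d(green, intr$x_um[q] / px + 0.5,
                                    y_um / px + 0.5,
                                    spec$msc_semi_axes[1] / px,
                                    spec$msc_semi_axes[2] / px, 0)
        rows[[length(rows) + 1]] <- data.frame(
          frame = t, id = intr$id[q], cx_px = intr$x_um[q] / px,
          cy_px = y_um / px, tilt_deg = 0,
          dist_edge_um = -intr$depth_um[q], status = "neighbor")
      }
    }

    if (!is.null(wall)) {
      vis <- wall[wall$appears <= t, , drop = FALSE]
      for (w in seq_len(nrow(vis))) {
        y_um <- cy_um + vis$y_off[w]
        green <- .render_ellipse_2d(green, vis$x_um[w] / px + 0.5,
                                    y_um / px + 0.5,
                                    1.5 * spec$msc_semi_axes[1] / px,
                                    1.5 * spec$msc_semi_axes[2] / px,
                                    vis$angle[w])
        rows[[length(rows) + 1]] <- data.frame(
          frame = t, id = vis$id[w], cx_px = vis$x_um[w] / px,
          cy_px = y_um / px, tilt_deg = vis$angle[w],
          dist_edge_um = -(R - abs(vis$y_off[w])), status = "intraluminal")
      }
    }

    # deep intraluminal objects (appear from day 2, excluded from analysis)
    if (t >= 2 && spec$n_deep_intraluminal > 0) {
      for (q in seq_len(spec$n_deep_intraluminal)) {
        x_um <- (0.3 + 0.35 * (q - 1)) * nx * px
        depth_um <- (spec$margin_px + 10) * px
        sd_side <- if (q %% 2 == 1) 1 else -1
        y_um <- cy_um + sd_side * (R - depth_um)
        green <- .render_ellipse_2d(green, x_um / px + 0.5, y_um / px + 0.5,
                                    spec$msc_semi_axes[1] / px,
                                    spec$msc_semi_axes[2] / px, 0)
        rows[[length(rows) + 1]] <- data.frame(
          frame = t, id = -100 - q, cx_px = x_um / px, cy_px = y_um / px,
          tilt_deg = 0, dist_edge_um = -depth_um, status = "intraluminal")
      }
    }

    red <- red0
    if (spec$psf_sigma > 0) {
      sig <- spec$psf_sigma / px
      red <- .blur2d(red, sig)
      green <- .blur2d(green, sig)
    }
    if (spec$poisson_scale > 0) {
      red <- matrix(rpois(length(red), pmax(red, 0) * spec$poisson_scale) /
                      spec$poisson_scale, nx, ny)
      green <- matrix(rpois(length(green), pmax(green, 0) * spec$poisson_scale) /
                        spec$poisson_scale, nx, ny)
    }
    if (spec$gaussian_sd > 0) {
      red <- red + matrix(rnorm(length(red), 0, spec$gaussian_sd), nx, ny)
      green <- green + matrix(rnorm(length(green), 0, spec$gaussian_sd), nx, ny)
    }
    frames[[t]] <- list(red = red, green = green)
    truth[[t]] <- do.call(rbind, rows)
  }

  truth <- do.call(rbind, truth)
  attr(truth, "margin_px") <- spec$margin_px
  attr(truth, "vessel") <- list(center_y_px = cy_um / px,
                                radius_um = R,
                                edge_upper_px = (cy_um - R) / px,
                                edge_lower_px = (cy_um + R) / px)
  series <- structure(list(frames = frames, pixel_size = px,
                           frame_days = seq_len(spec$frames)),
                      class = "image_series_2d")
  list(series = series, truth = truth)
}

# 2D separable Gaussian blur via the 3D kernel (nz = 1)
.blur2d <- function(img, sigma_px) {
  d <- c(dim(img), 1L)
  out <- smooth_gaussian_3d_cpp(array(img, d), d, c(sigma_px, sigma_px, 0))
  matrix(out, dim(img)[1], dim(img)[2])
}
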