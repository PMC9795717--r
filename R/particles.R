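# MSC particle analysis on the green channel: binarize, label connected
# components, fit ellipses via second central moments, and classify each
# object as neighbor / distant / intraluminal-excluded relative to the
# extracted vessel edges and the frozen day-1 margin band.

#' Detect MSC particles and fit ellipses
#'
#' Background subtraction (white top-hat), Otsu binarization, 8-connected
#' component labelling, removal of sub-threshold specks, then an ellipse
#' fit from second central moments per object. The tilt angle is the
#' undirected angle between the major axis and the vessel (x) axis,
#' folded into \[0, 90\] degrees.
#'
#' @param green_frame green-channel matrix `[x, y]`
#' @param params list: `tophat_radius` (px; 0 disables), `min_area`
#'   (px^2), `gauss_sigma` (px; 0 disables)
#' @return data.frame of class `particle_set`: `id`, `cx`, `cy` (px),
#'   `area_px`, `major_px`, `minor_px` (full axis lengths), `tilt_deg`.
#'   Zero rows is a valid result.
#' @export
detect_msc_particles <- function(green_frame, params = list()) {
  p <- modifyList(list(tophat_radius = 50, min_area = 20, gauss_sigma = 0),
                  params)
  img <- green_frame
  if (p$tophat_radius > 0) {
    brush <- EBImage::makeBrush(2 * p$tophat_radius + 1, "disc")
    img <- EBImage::imageData(EBImage::whiteTopHat(EBImage::Image(img), brush))
  }
  if (p$gauss_sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = p$gauss_sigma))
  rng <- range(img)
  empty <- structure(
    data.frame(id = integer(), cx = numeric(), cy = numeric(),
               area_px = numeric(), major_px = numeric(),
               minor_px = numeric(), tilt_deg = numeric()),
    class = c("particle_set", "data.frame"))
  if (diff(rng) == 0) return(empty)
  fg <- img > .otsu_threshold(img)
  if (!any(fg)) return(empty)

  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg)))
  nlab <- max(lab)
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(areas >= p$min_area)
  if (!length(keep)) return(empty)

  idx <- which(lab > 0)
  lv <- lab[idx]
  xs <- ((idx - 1) %% nrow(lab)) + 1
  ys <- ((idx - 1) %/% nrow(lab)) + 1
  rows <- lapply(seq_along(keep), function(j) {
    l <- keep[j]
    sel <- lv == l
    x <- xs[sel]; y <- ys[sel]
    cx <- mean(x); cy <- mean(y)
    mu20 <- mean((x - cx)^2) + 1 / 12   # + pixel-footprint correction
    mu02 <- mean((y - cy)^2) + 1 / 12
    mu11 <- mean((x - cx) * (y - cy))
    tr <- mu20 + mu02
    det <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
    l1 <- (tr + det) / 2
    l2 <- (tr - det) / 2
    theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    tilt <- abs(theta) %% 180
    if (tilt > 90) tilt <- 180 - tilt
    data.frame(id = j, cx = cx, cy = cy, area_px = length(x),
               major_px = 4 * sqrt(pmax(l1, 0)),
               minor_px = 4 * sqrt(pmax(l2, 0)), tilt_deg = tilt)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("particle_set", "data.frame")
  out
}

# signed distance (px) of each centroid outside the lumen:
# positive outside the nearer edge, negative inside
.edge_distance <- function(particles, edges) {
  n <- length(edges$upper_y)
  col <- pmin(pmax(round(particles$cx), 1), n)
  up <- edges$upper_y[col]
  lo <- edges$lower_y[col]
  ifelse(particles$cy < up, up - particles$cy,
         ifelse(particles$cy > lo, particles$cy - lo,
                -pmin(particles$cy - up, lo - particles$cy)))
}

#' Derive the frozen margin band from day-1 intraluminal objects
#'
#' Objects inside the lumen on day 1 are taken to be cells already in
#' contact with the wall; the deepest such centroid sets the intraluminal
#' margin `d_in`, and the extraluminal margin `d_out` is set to the same
#' distance. The margins are frozen and reused for all later frames of
#' the same chip. With no intraluminal object on day 1, the fallback is
#' the mean major-axis length of the day-1 objects (logged via a
#' message).
#'
#' @param day1_particles `particle_set` from the day-1 frame
#' @param day1_edges `vessel_edges` from the day-1 frame
#' @return object of class `margin_spec`: `d_in_px`, `d_out_px`,
#'   `frozen_from_day = 1`, `fallback_used`
#' @export
derive_margins <- function(day1_particles, day1_edges) {
  d <- .edge_distance(day1_particles, day1_edges)
  inside <- d < 0
  if (any(inside)) {
    d_in <- max(-d[inside])
    fallback <- FALSE
  } else {
    d_in <- mean(day1_particles$major_px)
    if (!is.finite(d_in)) stop("no day-1 objects to derive margins from")
    fallback <- TRUE
    message("no intraluminal object on day 1; margin fallback = mean major axis (",
            round(d_in, 1), " px)")
  }
  structure(list(d_in_px = d_in, d_out_px = d_in, frozen_from_day = 1L,
                 fallback_used = fallback),
            class = "margin_spec")
}

#' Classify particles as neighbor / distant / intraluminal-excluded
#'
#' A centroid between `edge - d_in` and `edge + d_out` is a neighbor
#' (both boundaries inclusive, ties resolved toward neighbor); beyond
#' `edge + d_out` it is distant; deeper than `d_in` inside the lumen the
#' object is excluded from analysis.
#'
#' @param particles `particle_set`
#' @param edges `vessel_edges` (same frame geometry)
#' @param margins frozen `margin_spec`
#' @return the particle set with columns `dist_edge_px` and `label`
#'   (factor: neighbor, distant, intraluminal)
#' @export
classify_particles <- function(particles, edges, margins) {
  stopifnot(inherits(margins, "margin_spec"))
  d <- .edge_distance(particles, edges)
  lab <- ifelse(d > margins$d_out_px, "distant",
                ifelse(d >= -margins$d_in_px, "neighbor", "intraluminal"))
  particles$dist_edge_px <- d
  particles$label <- factor(lab, levels = c("neighbor", "distant",
                                            "intraluminal"))
  particles
}

#' Tilt-angle histograms per location label
#'
#' @param particles labelled `particle_set` (see [classify_particles()])
#' @param bin_width histogram bin width in degrees
#' @return data.frame: `label`, `bin_left`, `bin_right`, `count`; counts
#'   per label sum to the number of objects with that label
#' @export
orientation_distribution <- function(particles, bin_width = 10) {
  stopifnot(!is.null(particles$label))
  breaks <- seq(0, 90, by = bin_width)
  if (max(breaks) < 90) breaks <- c(breaks, 90)
  rows <- lapply(levels(particles$label), function(l) {
    a <- particles$tilt_deg[particles$label == l]
    cnt <- if (length(a))
      graphics::hist(a, breaks = breaks, plot = FALSE, include.lowest = TRUE,
                     right = FALSE)$counts else integer(length(breaks) - 1)
    data.frame(label = l, bin_left = head(breaks, -1),
               bin_right = tail(breaks, -1), count = cnt)
  })
  do.call(rbind, rows)
}
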