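# Vessel-edge extraction from the red channel.
#
# Pipeline: background subtraction (white top-hat) -> Gaussian smoothing
# -> 1-D band-pass along the vessel axis via the discrete Fourier
# transform -> Otsu binarization -> per column, the most distant
# foreground pixel above and below the vessel centre -> running-median
# smoothing of the two edge traces.

.otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) stop("image is constant; no foreground after Otsu")
  vn <- (v - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(matrix(vn, ncol = 1)), range = c(0, 1))
  th * diff(rng) + rng[1]
}

# keep DC plus wavelengths in [min_wl, max_wl] along x (per y profile);
# DC is retained so a straight vessel (constant along x) survives the
# long-wavelength cut, which targets slow illumination gradients only
.bandpass_x <- function(img, min_wl, max_wl) {
  nx <- nrow(img)
  k <- seq_len(nx) - 1
  freq <- pmin(k, nx - k)              # cycles over the image
  wl <- ifelse(freq == 0, Inf, nx / freq)
  keep <- wl == Inf | (wl >= min_wl & wl <= max_wl)
  sp <- mvfft(img)
  sp[!keep, ] <- 0
  Re(mvfft(sp, inverse = TRUE)) / nx
}

#' Extract the parent vessel's upper and lower edges
#'
#' The vessel must run horizontally (along the image x axis). For each
#' column the uppermost foreground pixel above the vessel centre line and
#' the lowermost below it are taken as edge points; columns with no
#' foreground on one side are marked invalid and interpolated from
#' neighbouring columns, and both traces are smoothed with a running
#' median.
#'
#' @param red_frame red-channel matrix `[x, y]`
#' @param params list of tunables: `tophat_radius` (px; white top-hat
#'   background subtraction, 0 = disabled). Note the structuring element
#'   must be wider than the vessel for the vessel to survive a top-hat,
#'   so background subtraction is off by default here (unlike particle
#'   detection, where objects are small); enable it for real images with
#'   uneven illumination and a radius well above the vessel half-height.
#'   Further: `gauss_sigma` (px), `bandpass_min_wl` / `bandpass_max_wl`
#'   (px; max defaults to half the image width), `smooth_window`
#'   (columns, running-median)
#' @param center_y fixed vessel centre (px); when `NULL` it is estimated
#'   as the midpoint of the foreground extent. Freeze it from the first
#'   frame when processing a series.
#' @return object of class `vessel_edges`: `upper_y`, `lower_y` (px,
#'   smoothed), `center_y`, `valid` (columns with foreground on both
#'   sides)
#' @export
extract_vessel_edges <- function(red_frame, params = list(), center_y = NULL) {
  p <- modifyList(list(tophat_radius = 0, gauss_sigma = 2,
                       bandpass_min_wl = 8, bandpass_max_wl = NULL,
                       smooth_window = 15), params)
  nx <- nrow(red_frame); ny <- ncol(red_frame)
  if (is.null(p$bandpass_max_wl)) p$bandpass_max_wl <- nx / 2

  img <- red_frame
  if (p$tophat_radius > 0) {
    brush <- EBImage::makeBrush(2 * p$tophat_radius + 1, "disc")
    img <- EBImage::whiteTopHat(EBImage::Image(img), brush)
    img <- EBImage::imageData(img)
  }
  if (p$gauss_sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = p$gauss_sigma))
  img <- .bandpass_x(img, p$bandpass_min_wl, p$bandpass_max_wl)

  th <- .otsu_threshold(img)
  fg <- img > th
  if (!any(fg)) stop("image is constant; no foreground after Otsu")

  if (is.null(center_y)) {
    ys <- which(apply(fg, 2, any))
    center_y <- (min(ys) + max(ys)) / 2
  }

  upper <- lower <- rep(NA_real_, nx)
  for (i in seq_len(nx)) {
    yfg <- which(fg[i, ])
    up <- yfg[yfg < center_y]
    lo <- yfg[yfg > center_y]
    if (length(up)) upper[i] <- min(up)   # most distant above centre
    if (length(lo)) lower[i] <- max(lo)   # most distant below centre
  }
  valid <- !is.na(upper) & !is.na(lower)
  if (!any(valid)) stop("no column has foreground on both sides of the centre")
  fill <- function(v) {
    ok <- which(!is.na(v))
    approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
  }
  upper <- fill(upper); lower <- fill(lower)
  k <- p$smooth_window
  if (k %% 2 == 0) k <- k + 1
  if (k > 1 && nx > k) {
    upper <- runmed(upper, k, endrule = "median")
    lower <- runmed(lower, k, endrule = "median")
  }
  structure(list(upper_y = upper, lower_y = lower, center_y = center_y,
                 valid = valid),
            class = "vessel_edges")
}
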