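# File interchange: multi-page TIFF volumes with a JSON metadata
# sidecar, PLY meshes with per-vertex region/coverage/curvature
# properties, and run manifests.

#' Write a volume stack as multi-page TIFF + JSON sidecar
#'
#' Pages are ordered z-within-channel (channel order red, green, blue);
#' the sidecar `<path>.json` records dimensions, channel names and the
#' physical voxel size so the volume can be reconstructed exactly.
#'
#' @param vol `volume_stack`
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "volume_stack"))
  channels <- intersect(c("red", "green", "blue"), names(vol))
  pages <- list()
  for (ch in channels) {
    arr <- vol[[ch]]
    lo <- min(arr); hi <- max(arr)
    arr <- if (hi > lo) (arr - lo) / (hi - lo) else arr * 0
    for (k in seq_len(dim(arr)[3]))
      pages[[length(pages) + 1]] <- t(arr[, , k])   # tiff expects [row=y, col=x]
    attr(pages, ch) <- c(lo, hi)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(dim = dim(vol[[channels[1]]]), channels = channels,
               voxel_size_um = vol$voxel_size,
               ranges = lapply(channels, function(ch)
                 range(vol[[ch]])),
               page_order = "z within channel")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume stack written by [write_volume_tiff()]
#'
#' @param path TIFF path (expects the `.json` sidecar next to it)
#' @return `volume_stack`
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- meta$dim
  out <- list()
  i <- 0
  for (ci in seq_along(meta$channels)) {
    arr <- array(0, d)
    for (k in seq_len(d[3])) {
      i <- i + 1
      arr[, , k] <- t(pages[[i]])
    }
    rng <- if (is.matrix(meta$ranges)) meta$ranges[ci, ]
           else unlist(meta$ranges[[ci]])
    if (rng[2] > rng[1]) arr <- arr * (rng[2] - rng[1]) + rng[1]
    out[[meta$channels[ci]]] <- arr
  }
  out$voxel_size <- meta$voxel_size_um
  structure(out, class = "volume_stack")
}

#' Write a mesh as PLY
#'
#' Binary little-endian by default (ASCII available for inspection),
#' with per-vertex scalar properties `region` (0 = parent, 1 = sprout),
#' `covered` (0/1) and `mean_curvature` when present on the mesh.
#'
#' @param mesh `surface_mesh`
#' @param path output path
#' @param format `"binary_little_endian"` or `"ascii"`
#' @return `path`, invisibly
#' @export
write_mesh_ply <- function(mesh, path,
                           format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  has_region <- !is.null(mesh$region)
  has_cov <- !is.null(mesh$coverage)
  has_h <- !is.null(mesh$H)
  hdr <- c("ply", paste("format", format, "1.0"),
           "comment angiocross surface mesh",
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           if (has_region) "property uchar region",
           if (has_cov) "property uchar covered",
           if (has_h) "property float mean_curvature",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  region <- if (has_region) as.integer(mesh$region == "sprout")
  covered <- if (has_cov) as.integer(mesh$coverage == "covered")
  hvals <- if (has_h) { h <- mesh$H; h[!is.finite(h)] <- 0; h }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (format == "ascii") {
    vl <- paste(sprintf("%.6g", mesh$vertices[, 1]),
                sprintf("%.6g", mesh$vertices[, 2]),
                sprintf("%.6g", mesh$vertices[, 3]))
    if (has_region) vl <- paste(vl, region)
    if (has_cov) vl <- paste(vl, covered)
    if (has_h) vl <- paste(vl, sprintf("%.6g", hvals))
    writeLines(vl, con)
    writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  } else {
    # assemble interleaved vertex records as raw bytes, then write once
    coord_raw <- matrix(writeBin(as.numeric(t(mesh$vertices)), raw(),
                                 size = 4, endian = "little"), nrow = 12)
    rec <- coord_raw
    if (has_region) rec <- rbind(rec, matrix(as.raw(region), nrow = 1))
    if (has_cov) rec <- rbind(rec, matrix(as.raw(covered), nrow = 1))
    if (has_h) rec <- rbind(rec, matrix(writeBin(as.numeric(hvals), raw(),
                                                 size = 4,
                                                 endian = "little"),
                                        nrow = 4))
    writeBin(as.vector(rec), con)
    fint <- matrix(writeBin(as.integer(t(mesh$faces - 1L)), raw(), size = 4,
                            endian = "little"), nrow = 12)
    frec <- rbind(matrix(rep(as.raw(3), nf), nrow = 1), fint)
    writeBin(as.vector(frec), con)
  }
  invisible(path)
}

#' Write a run manifest as JSON
#'
#' @param dir run directory (created if needed)
#' @param ... named entries to record
#' @return manifest path, invisibly
#' @export
write_run_manifest <- function(dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "manifest.json")
  entries <- list(...)
  entries$written <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
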