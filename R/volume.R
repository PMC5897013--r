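#' Scalar CT volume
#'
#' A 3D intensity grid with per-axis voxel spacing in mm. Voxel
#' `(i, j, k)` (1-based) has its center at
#' `origin + spacing * (index - 0.5)`.
#'
#' @param grid 3D numeric array.
#' @param spacing voxel size per axis [mm].
#' @param origin world position of the grid corner [mm].
#' @return an object of class `scalar_volume`.
#' @export
scalar_volume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(grid)) == 3, all(spacing > 0))
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$grid), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' Segment the specimen foreground of a CT volume
#'
#' A specimen scanned in air separates cleanly from the background:
#' (1) seeded region growing (6-connectivity) over voxels at or above the
#' intensity threshold, seeded at the highest-intensity voxel;
#' (2) morphological opening then closing with ball kernels to remove
#' speckle and close small gaps; (3) hollow filling: background
#' components not connected to the volume border (enclosed cavities)
#' become foreground so the segmented specimen is solid.
#'
#' @param vol a [scalar_volume()].
#' @param threshold intensity threshold for region growing.
#' @param opening_radius,closing_radius ball radii in voxels (0 skips).
#' @param seed optional seed voxel (i, j, k); default is the
#'   highest-intensity voxel.
#' @return logical 3D array (the label volume).
#' @export
segment_foreground <- function(vol, threshold, opening_radius = 1,
                               closing_radius = 1, seed = NULL) {
  stopifnot(inherits(vol, "scalar_volume"))
  g <- vol$grid
  if (max(g) < threshold)
    stop("empty segmentation: no voxel reaches the threshold")
  if (is.null(seed)) {
    # pick the seed on a 3x3x3 box-smoothed copy so an isolated bright
    # noise voxel cannot win over the specimen body
    seed <- arrayInd(which.max(box_smooth3(g)), dim(g))[1, ]
  }
  dims <- dim(g)
  lab <- region_grow_cpp(as.numeric(g), dims, threshold, as.integer(seed))
  if (opening_radius > 0) {
    lab <- morph_ball_cpp(lab, dims, opening_radius, FALSE)
    lab <- morph_ball_cpp(lab, dims, opening_radius, TRUE)
  }
  if (closing_radius > 0) {
    lab <- morph_ball_cpp(lab, dims, closing_radius, TRUE)
    lab <- morph_ball_cpp(lab, dims, closing_radius, FALSE)
  }
  lab <- hollow_fill_cpp(lab, dims)
  array(lab, dims)
}

#' Extract a triangle mesh from a binary label volume
#'
#' Isosurface of the (optionally box-smoothed) indicator field at the
#' 0.5 level. Cells are decomposed into six tetrahedra sharing the main
#' diagonal with linear interpolation of the level crossing along voxel
#' edges; the decomposition is translation-invariant, so the mesh is
#' watertight and every edge is shared by exactly two faces. The volume
#' is treated as padded with one background layer, so surfaces touching
#' the border still close. One round of 3x3x3 box smoothing (default)
#' removes the staircase faceting of the raw binary field; set
#' `smooth_iters = 0` to isosurface the indicator directly (thin
#' single-voxel features survive only without smoothing).
#'
#' @param labels logical 3D array.
#' @param spacing voxel size per axis [mm].
#' @param origin world position of the grid corner [mm].
#' @param smooth_iters rounds of box smoothing of the indicator field.
#' @return a [triangle_mesh()] in mm units.
#' @export
extract_surface <- function(labels, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0), smooth_iters = 1) {
  if (!any(labels)) stop("empty label volume")
  field <- array(as.numeric(labels), dim(labels))
  if (smooth_iters > 0)
    for (i in seq_len(smooth_iters)) field <- box_smooth3(field)
  r <- marching_tets_cpp(as.numeric(field), dim(labels),
                         as.numeric(spacing), as.numeric(origin), 0.5)
  triangle_mesh(r$vertices, r$faces)
}

# mean over the 3x3x3 neighborhood (zero-padded), used for seeding
box_smooth3 <- function(g) {
  d <- dim(g)
  acc <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    acc[xs, ys, zs] <- acc[xs, ys, zs] + g[xs - dx, ys - dy, zs - dz]
  }
  acc / 27
}

#' Read / write volumes as multipage TIFF or raw + JSON header
#'
#' TIFF: one page per z-slice, intensities in `[0, 1]` (tiff package
#' convention). Raw: `uint8` or `uint16` little-endian with a JSON
#' header `{"shape": [x, y, z], "spacing_mm": [...], "dtype": ...}`
#' stored alongside as `<path>.json`.
#'
#' @param path volume file (`.tif`/`.tiff` or `.raw`).
#' @return a [scalar_volume()].
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    grid <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) grid[, , k] <- pages[[k]]
    hdr <- paste0(path, ".json")
    spacing <- c(1, 1, 1)
    if (file.exists(hdr))
      spacing <- jsonlite::fromJSON(hdr)$spacing_mm
    scalar_volume(grid, spacing)
  } else if (ext == "raw") {
    hdr <- jsonlite::fromJSON(paste0(path, ".json"))
    n <- prod(hdr$shape)
    size <- if (hdr$dtype == "uint16") 2L else 1L
    v <- readBin(path, "integer", n = n, size = size, signed = FALSE,
                 endian = "little")
    scalar_volume(array(v, hdr$shape), hdr$spacing_mm)
  } else stop("unsupported volume format: ", ext)
}

#' @rdname read_volume
#' @param vol a [scalar_volume()]; TIFF output rescales intensities to
#'   `[0, 1]` by the maximum; raw output writes integers unchanged.
#' @param dtype for raw output: `"uint8"` or `"uint16"`.
#' @export
write_volume <- function(vol, path, dtype = "uint16") {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    mx <- max(vol$grid)
    if (mx <= 0) mx <- 1
    pages <- lapply(seq_len(dim(vol$grid)[3]),
                    function(k) vol$grid[, , k] / mx)
    tiff::writeTIFF(pages, path)
    jsonlite::write_json(list(shape = dim(vol$grid),
                              spacing_mm = vol$spacing, dtype = "float"),
                         paste0(path, ".json"), auto_unbox = FALSE)
  } else if (ext == "raw") {
    size <- if (dtype == "uint16") 2L else 1L
    writeBin(as.integer(round(vol$grid)), path, size = size,
             endian = "little")
    jsonlite::write_json(list(shape = dim(vol$grid),
                              spacing_mm = vol$spacing, dtype = dtype),
                         paste0(path, ".json"), auto_unbox = FALSE)
  } else stop("unsupported volume format: ", ext)
  invisible(path)
}
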