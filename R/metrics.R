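#' Boundary pixels of a binary silhouette
#'
#' A boundary pixel is a foreground pixel with at least one 4-neighbor in
#' the background; the image border counts as background.
#'
#' @param img logical matrix (TRUE = foreground).
#' @return k x 2 integer matrix of (row, col) indices.
#' @export
extract_boundary <- function(img) {
  if (!any(img)) stop("empty silhouette: no foreground pixels")
  boundary_pixels_cpp(img)
}

#' Euclidean distance transform to the silhouette boundary
#'
#' Each pixel holds the exact Euclidean distance in pixels to the nearest
#' boundary pixel of `img` (the I^d image of the matching metric).
#'
#' @param img logical matrix with at least one foreground pixel.
#' @return numeric matrix of distances, zero exactly on the boundary.
#' @export
distance_field <- function(img) {
  if (!any(img)) stop("empty silhouette: no foreground pixels")
  distance_field_cpp(img)
}

#' Directed boundary-distance metric between two silhouettes
#'
#' The matching cost `d(I, R) = (1/|B_r|) sum_{p in B_r} I^d(p)`: the
#' mean, over the boundary pixels of the rendered silhouette, of the
#' photograph's boundary distance transform. Zero iff every render
#' boundary pixel lies on the photo boundary.
#'
#' @param photo binarized photograph (logical matrix).
#' @param render rendered silhouette (logical matrix, same size).
#' @param photo_dt optional precomputed [distance_field()] of `photo`.
#' @return non-negative cost in pixels.
#' @export
silhouette_distance <- function(photo, render, photo_dt = NULL) {
  if (is.null(photo_dt)) {
    if (!identical(dim(photo), dim(render))) stop("image size mismatch")
    photo_dt <- distance_field(photo)
  } else if (!identical(dim(photo_dt), dim(render))) stop("image size mismatch")
  b <- extract_boundary(render)
  mean(photo_dt[b])
}

foreground_centroid <- function(img) {
  w <- which(img, arr.ind = TRUE)
  if (nrow(w) == 0) stop("empty silhouette: no foreground pixels")
  colMeans(w)
}

#' Best-fitting 2D rotation and translation between silhouettes
#'
#' The coarse-search variant of the matching metric: the render boundary
#' is translated so its foreground mass center g_r lands on the photo's
#' mass center g_t, rotated by alpha about it (counter-clockwise in
#' screen coordinates, y up), and the photo's distance field is averaged
#' under the transformed boundary. Alpha is searched exhaustively over
#' `[0, 360)` degrees in 1-degree steps; samples falling outside the
#' image read the nearest border value.
#'
#' @inheritParams silhouette_distance
#' @return list with `alpha` (radians, in `[0, 2*pi)`), `g_t`, `g_r`
#'   (row/col mass centers), `g_r_rot` (g_r rotated about the image
#'   center by alpha, row/col), and `cost` (mean boundary distance, px).
#' @export
aligned_distance <- function(photo, render, photo_dt = NULL) {
  if (!identical(dim(photo), dim(render))) stop("image size mismatch")
  if (is.null(photo_dt)) photo_dt <- distance_field(photo)
  g_t <- foreground_centroid(photo)
  g_r <- foreground_centroid(render)
  b <- extract_boundary(render)
  res <- alpha_search_cpp(photo_dt, g_t, matrix(as.numeric(b), ncol = 2),
                          g_r)
  alpha <- res[2] * pi / 180
  structure(list(alpha = alpha, g_t = g_t, g_r = g_r,
                 g_r_rot = rotate_about_center(g_r, alpha, dim(photo)),
                 cost = res[1]),
            class = "alignment_result")
}

# rotate a (row, col) point about the image center by alpha, CCW in
# screen coordinates (y up); returns (row, col)
rotate_about_center <- function(rc, alpha, dims) {
  cx <- dims[2] / 2; cy <- dims[1] / 2
  sx <- rc[2] - cx; sy <- cy - rc[1]
  rx <- cos(alpha) * sx - sin(alpha) * sy
  ry <- sin(alpha) * sx + cos(alpha) * sy
  c(row = cy - ry, col = cx + rx)
}

#' Initial camera rotations from a 2D alignment
#'
#' Converts the best 2D rotation/translation found by
#' [aligned_distance()] into the three local camera rotations: the roll
#' absorbs the image rotation (`delta_x = -alpha`) and the yaw/pitch
#' absorb the horizontal/vertical image offsets through
#' `delta = atan(offset / f)`, all in screen coordinates (y up) with the
#' focal length in pixels.
#'
#' @param align an alignment from [aligned_distance()].
#' @param intr a [camera_intrinsics()] (for `focal_px` and image center).
#' @return named numeric vector `(delta_x, delta_y, delta_z)` [rad];
#'   `delta_x` wrapped into `[0, 2*pi)`.
#' @export
rotation_from_alignment <- function(align, intr) {
  f <- intr$focal_px
  cx <- intr$width / 2; cy <- intr$height / 2
  gt <- unname(c(align$g_t[2] - cx, cy - align$g_t[1]))   # screen (x, y)
  grr <- unname(c(align$g_r_rot[2] - cx, cy - align$g_r_rot[1]))
  c(delta_x = (-align$alpha) %% (2 * pi),
    delta_y = atan((-grr[1] + gt[1]) / f),
    delta_z = atan((-grr[2] + gt[2]) / f))
}

#' Read / write binary masks as 8-bit PNG
#'
#' Foreground is any pixel above half intensity (masks are written with
#' 0 = background, 255 = foreground).
#'
#' @param path PNG file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' @rdname read_mask
#' @param img logical matrix to write.
#' @export
write_mask <- function(img, path) {
  png::writePNG(img * 1, path)
  invisible(path)
}
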