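#' Axis-aligned 3D rotation matrix
#'
#' Right-handed active rotation about a coordinate axis. The convention is
#' fixed for the whole package: `rotation_matrix("y", b)` maps
#' `(1,0,0)` to `(cos b, 0, -sin b)`.
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param angle rotation angle in radians.
#' @return a 3x3 orthonormal matrix with determinant 1.
#' @export
rotation_matrix <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  switch(match.arg(axis, c("x", "y", "z")),
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Six-parameter camera pose
#'
#' A camera is placed on a sphere centered at the mass center of the
#' specimen mesh: `theta` (azimuth) and `phi` (altitude) select the
#' direction, `r` the distance in mm. Three local rotations
#' `(delta_x, delta_y, delta_z)` (roll about the viewing ray, and the
#' small yaw/pitch that shift the image horizontally/vertically) complete
#' the six degrees of freedom.
#'
#' @param theta,phi azimuth and altitude angles in radians.
#' @param r camera-to-center distance in mm; must be positive.
#' @param delta_x,delta_y,delta_z local camera rotations in radians.
#' @return an object of class `camera_pose`.
#' @export
camera_pose <- function(theta = 0, phi = 0, r, delta_x = 0, delta_y = 0,
                        delta_z = 0) {
  vals <- c(theta = theta, phi = phi, r = r, delta_x = delta_x,
            delta_y = delta_y, delta_z = delta_z)
  if (!all(is.finite(vals))) stop("invalid pose: non-finite parameter")
  if (r <= 0) stop("invalid pose: r must be positive")
  structure(as.list(vals), class = "camera_pose")
}

#' @export
print.camera_pose <- function(x, ...) {
  cat(sprintf(
    "<camera_pose> theta=%.4f phi=%.4f r=%.2f mm delta=(%.4f, %.4f, %.4f)\n",
    x$theta, x$phi, x$r, x$delta_x, x$delta_y, x$delta_z))
  invisible(x)
}

pose_to_vector <- function(pose) {
  c(pose$theta, pose$phi, pose$r, pose$delta_x, pose$delta_y, pose$delta_z)
}

vector_to_pose <- function(v) {
  camera_pose(v[1], v[2], v[3], v[4], v[5], v[6])
}

#' Orthonormal camera frame from a pose
#'
#' Builds the camera coordinate system: position
#' `pos = R_y(theta) R_z(phi) (r,0,0)'`, viewing ray
#' `ray = R_y(theta) R_z(phi) R_x(dx) R_y(dy) R_z(dz) (-1,0,0)'` and up
#' vector (same rotation chain applied to `(0,1,0)'`). The camera space
#' basis is `(right, up, ray)` with `right = ray x up`; projection divides
#' by the camera-space z (along `ray`).
#'
#' @param pose a [camera_pose()].
#' @return list with unit vectors `ray`, `up`, `right` and `pos` (mm),
#'   all relative to the mesh mass center.
#' @export
camera_frame <- function(pose) {
  stopifnot(inherits(pose, "camera_pose"))
  Rg <- rotation_matrix("y", pose$theta) %*% rotation_matrix("z", pose$phi)
  Rl <- Rg %*% rotation_matrix("x", pose$delta_x) %*%
    rotation_matrix("y", pose$delta_y) %*% rotation_matrix("z", pose$delta_z)
  pos <- drop(Rg %*% c(pose$r, 0, 0))
  ray <- drop(Rl %*% c(-1, 0, 0))
  up <- drop(Rl %*% c(0, 1, 0))
  list(pos = pos, ray = ray, up = up, right = cross3(ray, up))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Pinhole camera intrinsics
#'
#' Focal length in pixel units plus the image size. When built from a
#' physical lens, `focal_px = focal_mm / sensor_width_mm * width`.
#'
#' @param width,height image size in pixels.
#' @param focal_px focal length in pixels (give this or the pair below).
#' @param focal_mm,sensor_width_mm physical focal length and sensor width.
#' @return an object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(width, height, focal_px = NULL,
                              focal_mm = NULL, sensor_width_mm = NULL) {
  if (is.null(focal_px)) {
    if (is.null(focal_mm) || is.null(sensor_width_mm))
      stop("give focal_px or both focal_mm and sensor_width_mm")
    focal_px <- focal_mm / sensor_width_mm * width
  }
  if (focal_px <= 0) stop("focal_px must be positive")
  structure(list(focal_px = focal_px, width = as.integer(width),
                 height = as.integer(height)),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> f=%.2f px, %d x %d\n",
              x$focal_px, x$width, x$height))
  invisible(x)
}

#' Project camera-space points to the screen
#'
#' Pinhole projection `(x', y') = (x f / z, y f / z)` in pixel units.
#' Screen x grows to the right, screen y up, origin on the optical axis
#' (image center).
#'
#' @param p_cam n x 3 matrix (or length-3 vector) of camera-space points;
#'   the depth coordinate z must be positive.
#' @param intr a [camera_intrinsics()].
#' @return n x 2 matrix of screen positions in pixels.
#' @export
project_points <- function(p_cam, intr) {
  p_cam <- rbind(p_cam)
  if (any(p_cam[, 3] <= 0)) stop("point behind camera (z <= 0)")
  cbind(p_cam[, 1] * intr$focal_px / p_cam[, 3],
        p_cam[, 2] * intr$focal_px / p_cam[, 3])
}

#' Convert screen coordinates to continuous pixel coordinates
#'
#' The image origin is the top-left corner; the column coordinate grows
#' with screen +x and the row coordinate with screen -y; the principal
#' point is the image center. Pixel (i, j) covers
#' `[i-1, i] x [j-1, j]` with its center at `(i - 0.5, j - 0.5)`.
#'
#' @param xy n x 2 matrix of screen positions from [project_points()].
#' @param intr a [camera_intrinsics()].
#' @return n x 2 matrix of continuous `(row, col)` pixel coordinates.
#' @export
screen_to_pixel <- function(xy, intr) {
  xy <- rbind(xy)
  cbind(intr$height / 2 - xy[, 2], intr$width / 2 + xy[, 1])
}

#' Transform world points into camera space
#'
#' @param points n x 3 matrix of points in mesh coordinates (mm).
#' @param frame a camera frame from [camera_frame()].
#' @param center mass center of the mesh (origin of the camera sphere).
#' @return n x 3 matrix of camera-space coordinates.
#' @export
world_to_camera <- function(points, frame, center = c(0, 0, 0)) {
  q <- sweep(rbind(points), 2, center + frame$pos)
  q %*% cbind(frame$right, frame$up, frame$ray)
}
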