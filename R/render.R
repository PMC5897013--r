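#' Render a binary silhouette of a mesh
#'
#' Software-rasterizes the mesh from a camera pose: a pixel is foreground
#' iff a triangle (front- or back-facing) covers its center at positive
#' camera-space depth. Used both for the matching metric R(c, M) and for
#' visibility testing during texturing.
#'
#' @param mesh a [triangle_mesh()].
#' @param pose a [camera_pose()].
#' @param intr a [camera_intrinsics()].
#' @return logical `height x width` matrix (TRUE = foreground).
#' @export
render_silhouette <- function(mesh, pose, intr) {
  render_views(mesh, pose, intr)$silhouette
}

#' Render silhouette, depth and normal-dot maps
#'
#' As [render_silhouette()], but also returns the depth buffer (camera-z
#' of the nearest hit, mm; background = `Inf`), the per-pixel dot product
#' `-(view ray . surface normal)` of the nearest hit (the I^n map used to
#' prefer front-facing texture during stitching), and the face index map.
#'
#' @inheritParams render_silhouette
#' @return list with `silhouette`, `depth`, `normal_dot`, `face`.
#' @export
render_views <- function(mesh, pose, intr) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  frame <- camera_frame(pose)
  vc <- world_to_camera(mesh$vertices, frame, mesh$mass_center)
  nc <- mesh$face_normals %*% cbind(frame$right, frame$up, frame$ray)
  r <- rasterize_mesh_cpp(vc, mesh$faces - 1L, nc, intr$focal_px,
                          intr$width, intr$height)
  list(silhouette = is.finite(r$depth), depth = r$depth,
       normal_dot = r$normal_dot, face = r$face)
}

#' Render a flat-colored image of a mesh
#'
#' Each face is painted with a constant color; used by the synthetic
#' fixture generator to produce color "photographs" with exactly known
#' ground truth.
#'
#' @inheritParams render_silhouette
#' @param face_colors m x 3 matrix of RGB in `[0,1]`, one row per face.
#' @param background background color (length 3).
#' @return `height x width x 3` array of RGB in `[0,1]`.
#' @export
render_flat_color <- function(mesh, pose, intr, face_colors,
                              background = c(0, 0, 0)) {
  v <- render_views(mesh, pose, intr)
  img <- array(rep(background, each = intr$height * intr$width),
               dim = c(intr$height, intr$width, 3))
  hit <- v$face > 0
  for (d in 1:3) {
    ch <- img[, , d]
    ch[hit] <- face_colors[v$face[hit], d]
    img[, , d] <- ch
  }
  img
}
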