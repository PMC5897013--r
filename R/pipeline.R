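#' Reduce an image or mask by an integer factor
#'
#' Block-averaging reduction (the photographs are matched at 1/8 of the
#' camera resolution: 3696 x 2448 becomes 462 x 306). Masks are reduced
#' by majority (mean coverage > 0.5).
#'
#' @param img matrix (mask) or `h x w x 3` array (RGB).
#' @param factor integer reduction factor; image dimensions must be
#'   divisible by it.
#' @return the reduced image.
#' @export
reduce_image <- function(img, factor = 8) {
  d <- dim(img)
  if (d[1] %% factor != 0 || d[2] %% factor != 0)
    stop("image size not divisible by the reduction factor")
  h <- d[1] %/% factor; w <- d[2] %/% factor
  red1 <- function(m) {
    m <- matrix(colMeans(matrix(m, factor)), h, d[2])
    t(matrix(colMeans(matrix(t(m), factor)), w, h))
  }
  if (length(d) == 2) {
    out <- red1(img * 1)
    if (is.logical(img)) out > 0.5 else out
  } else {
    out <- array(0, c(h, w, d[3]))
    for (k in seq_len(d[3])) out[, , k] <- red1(img[, , k])
    out
  }
}

#' Run the full digitization pipeline
#'
#' Executes the whole chain: load (or segment) the specimen mesh, build
#' the UV atlas, estimate a camera pose per photograph by silhouette
#' matching (photographs with cost at or above the discard threshold are
#' excluded), back-project the accepted photographs, merge the textures
#' with graph-cut stitching, fill never-covered texels and optionally
#' synthesize texture in them, and write the OBJ/MTL/PNG bundle plus
#' JSON reports.
#'
#' @param config a named list (or path to a JSON file) with entries:
#'   `mesh` (path) or `volume` (path) + `threshold`; `photos`: list of
#'   entries with `mask` (PNG path) and optional `image` (PNG path);
#'   `intrinsics`: list with `width`, `height` and `focal_px` or
#'   `focal_mm` + `sensor_width_mm`; `r0`; optional `reduce_factor`,
#'   `atlas_resolution`, `max_normal_cone_deg`, `stitch_w`,
#'   `synthesis` (logical), `n_sphere`, `n_hill`, `n_starts`, `seed`;
#'   `out_dir`.
#' @return invisibly, the run report (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = FALSE)
  cfgv <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfgv("seed", 1L)

  # --- mesh ---
  mesh <- if (!is.null(config$mesh)) {
    read_mesh(config$mesh)
  } else if (!is.null(config$volume)) {
    vol <- read_volume(config$volume)
    labels <- segment_foreground(vol, threshold = config$threshold,
                                 opening_radius = cfgv("opening_radius", 1),
                                 closing_radius = cfgv("closing_radius", 1))
    extract_surface(labels, vol$spacing, vol$origin)
  } else stop("config needs a mesh or a volume entry")

  # --- atlas ---
  charts <- segment_charts(mesh, cfgv("max_normal_cone_deg", 35))
  layout <- flatten_and_pack(mesh, charts,
                             resolution = cfgv("atlas_resolution", 512))

  # --- intrinsics and photographs ---
  ic <- config$intrinsics
  intr <- camera_intrinsics(width = ic$width, height = ic$height,
                            focal_px = ic$focal_px,
                            focal_mm = ic$focal_mm,
                            sensor_width_mm = ic$sensor_width_mm)
  red <- cfgv("reduce_factor", 1)
  if (red > 1)
    intr <- camera_intrinsics(width = intr$width %/% red,
                              height = intr$height %/% red,
                              focal_px = intr$focal_px / red)
  photos <- lapply(config$photos, function(p) {
    mask <- read_mask(p$mask)
    img <- if (!is.null(p$image)) {
      a <- png::readPNG(p$image)
      if (length(dim(a)) == 2) array(rep(a, 3), c(dim(a), 3)) else a[, , 1:3]
    } else NULL
    if (red > 1) {
      mask <- reduce_image(mask, red)
      if (!is.null(img)) img <- reduce_image(img, red)
    }
    list(name = basename(p$mask), mask = mask, image = img)
  })

  # --- pose estimation ---
  scfg <- search_config(r0 = config$r0,
                        n_sphere = cfgv("n_sphere", 2562),
                        n_hill = cfgv("n_hill", 1000),
                        n_starts = cfgv("n_starts", 5),
                        rng_seed = seed)
  cache <- pose_search_cache(mesh, intr, scfg)
  estimates <- vector("list", length(photos))
  for (i in seq_along(photos)) {
    scfg$rng_seed <- seed + i * 1000L
    estimates[[i]] <- estimate_camera_pose(photos[[i]]$mask, mesh, intr,
                                           scfg, cache)
    message(sprintf("photo %s: cost %.4f (%s)", photos[[i]]$name,
                    estimates[[i]]$cost,
                    if (estimates[[i]]$accepted) "accepted" else "discarded"))
  }
  used <- which(vapply(estimates, function(e) e$accepted, TRUE))
  if (length(used) == 0)
    stop("zero accepted photographs; costs: ",
         paste(sprintf("%.3f", vapply(estimates, function(e) e$cost, 0)),
               collapse = ", "))

  # --- texturing ---
  textures <- lapply(used, function(i) {
    img <- photos[[i]]$image
    if (is.null(img)) # mask-only runs still exercise the full chain
      img <- array(rep(photos[[i]]$mask * 1, 3),
                   c(dim(photos[[i]]$mask), 3))
    backproject(img, photos[[i]]$mask, estimates[[i]], mesh, layout, intr,
                photo_id = i,
                sample_mode = cfgv("sample_mode", "bilinear"))
  })
  names(textures) <- vapply(used, function(i) photos[[i]]$name, "")
  merged <- merge_all(textures, layout, w = cfgv("stitch_w", 1))
  merged <- fill_and_smooth(merged, layout,
                            smooth_iters = cfgv("smooth_iters", 10))
  if (isTRUE(cfgv("synthesis", FALSE)))
    merged <- synthesize_patches(merged, mesh, layout,
                                 n_ref = cfgv("n_ref", 2000),
                                 n_iters = cfgv("synth_iters", 3),
                                 rng_seed = seed)

  # --- outputs ---
  obj <- file.path(out_dir, "model.obj")
  write_textured_obj(mesh, layout, obj, texture_png = "texture.png")
  write_texture_png(merged, file.path(out_dir, "texture.png"))
  write_source_map_png(merged, file.path(out_dir, "source_map.png"))
  poses <- lapply(seq_along(estimates), function(i) {
    e <- estimates[[i]]
    list(photo = photos[[i]]$name,
         pose = unclass(e$pose), cost = e$cost, accepted = e$accepted)
  })
  jsonlite::write_json(poses, file.path(out_dir, "poses.json"),
                       auto_unbox = TRUE, digits = NA)
  report <- list(seed = seed,
                 n_photos = length(photos),
                 n_used = length(used),
                 used = vapply(used, function(i) photos[[i]]$name, ""),
                 costs = vapply(estimates, function(e) e$cost, 0),
                 accepted = vapply(estimates, function(e) e$accepted, TRUE),
                 median_used_cost = median(
                   vapply(estimates[used], function(e) e$cost, 0)),
                 atlas_resolution = layout$resolution,
                 covered_texels = sum(merged$covered))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Write the textured OBJ/MTL bundle
#'
#' OBJ with per-corner texture coordinates (`vt`, `f v/vt`) referencing
#' an MTL file and texture image, loadable in standard mesh viewers.
#'
#' @param mesh the [triangle_mesh()].
#' @param layout the `atlas_layout` holding per-corner UVs.
#' @param path output OBJ path (`.mtl` written alongside).
#' @param texture_png texture image filename referenced by the MTL.
#' @return the path, invisibly.
#' @export
write_textured_obj <- function(mesh, layout, path, texture_png = "texture.png") {
  fu <- layout$face_uv
  mtl <- sub("\\.obj$", ".mtl", path)
  writeLines(c("newmtl textured", "Ka 1 1 1", "Kd 1 1 1",
               paste("map_Kd", texture_png)), mtl)
  # order faces as in the mesh for the v/vt records
  ord <- order(fu$fid)
  tri_uv <- fu$tri[ord, , drop = FALSE]
  tri_v <- mesh$faces[fu$fid[ord], , drop = FALSE]
  out <- c(paste("mtllib", basename(mtl)),
           sprintf("v %.8g %.8g %.8g", mesh$vertices[, 1],
                   mesh$vertices[, 2], mesh$vertices[, 3]),
           sprintf("vt %.8g %.8g", fu$uv[, 1], fu$uv[, 2]),
           "usemtl textured",
           sprintf("f %d/%d %d/%d %d/%d",
                   tri_v[, 1], tri_uv[, 1], tri_v[, 2], tri_uv[, 2],
                   tri_v[, 3], tri_uv[, 3]))
  writeLines(out, path)
  invisible(path)
}

#' Write the texture atlas / source-id map as PNG
#'
#' The source map encodes photo ids as gray levels (id / 255); texels
#' synthesized by occlusion fill carry the reserved value 254/255.
#'
#' @param atlas a `texture_atlas`.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_texture_png <- function(atlas, path) {
  png::writePNG(pmin(pmax(atlas$color, 0), 1), path)
  invisible(path)
}

#' @rdname write_texture_png
#' @export
write_source_map_png <- function(atlas, path) {
  src <- atlas$source_id
  src[src == -1L] <- 254L
  png::writePNG(src / 255, path)
  invisible(path)
}
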