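#' Back-project a photograph into the texture atlas
#'
#' For every texel of the atlas the corresponding surface point is
#' projected into the photograph with the estimated camera. The texel is
#' covered iff the projected pixel falls in the mask foreground, the
#' point passes a depth-buffer visibility test against the mesh rendered
#' from the same camera, and the surface faces the camera
#' (`-ray . normal > facing_eps`). Colors are sampled bilinearly; the
#' per-texel `-ray . normal` (the I^n map) is stored for stitching.
#'
#' @param photo `h x w x 3` RGB array in `[0,1]`.
#' @param mask logical `h x w` foreground mask of the photo.
#' @param pose a `pose_estimate` (must be accepted) or [camera_pose()].
#' @param mesh the textured [triangle_mesh()].
#' @param layout an `atlas_layout` from [flatten_and_pack()].
#' @param intr [camera_intrinsics()] of the photograph.
#' @param facing_eps minimum `-ray . normal` for a texel to be covered.
#' @param depth_tol visibility slack [mm] against the depth buffer.
#' @param photo_id integer id recorded in the `source_id` map.
#' @param sample_mode `"bilinear"` (default) or `"nearest"`; nearest
#'   keeps flat-colored regions exact and suits piecewise-constant
#'   synthetic photographs.
#' @return a `texture_atlas`: list with `color` (res x res x 3),
#'   `normal_dot`, `covered`, `source_id`, `pose_cost`, `resolution`.
#' @export
backproject <- function(photo, mask, pose, mesh, layout, intr,
                        facing_eps = 0.01, depth_tol = 1.0,
                        photo_id = 1L,
                        sample_mode = c("bilinear", "nearest")) {
  sample_mode <- match.arg(sample_mode)
  if (inherits(pose, "pose_estimate")) {
    if (!pose$accepted)
      stop("pose was rejected (cost >= discard threshold); not texturing")
    pcost <- pose$cost
    pose <- pose$pose
  } else pcost <- NA_real_
  res <- layout$resolution
  idx <- which(layout$face > 0)
  fid <- layout$face[idx]
  b <- cbind(layout$bary[[1]][idx], layout$bary[[2]][idx],
             layout$bary[[3]][idx])
  v1 <- mesh$vertices[mesh$faces[fid, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[fid, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[fid, 3], , drop = FALSE]
  pts <- v1 * b[, 1] + v2 * b[, 2] + v3 * b[, 3]
  frame <- camera_frame(pose)
  pc <- world_to_camera(pts, frame, mesh$mass_center)
  ok <- pc[, 3] > 0
  rc <- matrix(NA_real_, length(idx), 2)
  rc[ok, ] <- screen_to_pixel(
    cbind(pc[ok, 1] * intr$focal_px / pc[ok, 3],
          pc[ok, 2] * intr$focal_px / pc[ok, 3]), intr)
  inside <- ok & rc[, 1] >= 0.5 & rc[, 1] <= intr$height - 0.5 &
    rc[, 2] >= 0.5 & rc[, 2] <= intr$width - 0.5
  inside[is.na(inside)] <- FALSE
  # mask test at the nearest pixel
  ri <- pmin(pmax(round(rc[, 1] + 0.5), 1L), intr$height)
  ci <- pmin(pmax(round(rc[, 2] + 0.5), 1L), intr$width)
  inmask <- inside
  inmask[inside] <- mask[cbind(ri[inside], ci[inside])]
  # visibility: depth buffer from this camera
  views <- render_views(mesh, pose, intr)
  vis <- inmask
  vis[inmask] <- pc[inmask, 3] <= views$depth[cbind(ri[inmask], ci[inmask])] +
    depth_tol
  # facing test
  ncam <- mesh$face_normals[fid, , drop = FALSE] %*%
    cbind(frame$right, frame$up, frame$ray)
  raylen <- sqrt(rowSums(pc^2))
  ndot <- -rowSums(pc * ncam) / pmax(raylen, 1e-12)
  cov <- vis & ndot > facing_eps
  # bilinear color sample
  color <- array(0, c(res, res, 3))
  ndmat <- matrix(0, res, res)
  covm <- matrix(FALSE, res, res)
  src <- matrix(0L, res, res)
  sel <- which(cov)
  if (length(sel)) {
    col_s <- if (sample_mode == "bilinear")
      bilinear_rgb(photo, rc[sel, 1, drop = FALSE],
                   rc[sel, 2, drop = FALSE])
    else
      cbind(photo[, , 1][cbind(ri[sel], ci[sel])],
            photo[, , 2][cbind(ri[sel], ci[sel])],
            photo[, , 3][cbind(ri[sel], ci[sel])])
    for (d in 1:3) {
      ch <- color[, , d]
      ch[idx[sel]] <- col_s[, d]
      color[, , d] <- ch
    }
    ndmat[idx[sel]] <- ndot[sel]
    covm[idx[sel]] <- TRUE
    src[idx[sel]] <- photo_id
  }
  structure(list(color = color, normal_dot = ndmat, covered = covm,
                 source_id = src, pose_cost = pcost, resolution = res),
            class = "texture_atlas")
}

# bilinear RGB sample at continuous (row, col) pixel-center coordinates
bilinear_rgb <- function(img, row, col) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- pmin(pmax(row + 0.5, 1), h)
  c_ <- pmin(pmax(col + 0.5, 1), w)
  r0 <- pmin(floor(r), h - 1); c0 <- pmin(floor(c_), w - 1)
  fr <- r - r0; fc <- c_ - c0
  out <- matrix(0, length(r), 3)
  for (d in 1:3) {
    ch <- img[, , d]
    out[, d] <- (1 - fr) * ((1 - fc) * ch[cbind(r0, c0)] +
                            fc * ch[cbind(r0, c0 + 1)]) +
                fr * ((1 - fc) * ch[cbind(r0 + 1, c0)] +
                      fc * ch[cbind(r0 + 1, c0 + 1)])
  }
  out
}

#' @export
print.texture_atlas <- function(x, ...) {
  cat(sprintf("<texture_atlas> %d x %d, %d covered texels\n",
              x$resolution, x$resolution, sum(x$covered)))
  invisible(x)
}

#' Stitch two textures with a normal-aware graph cut
#'
#' Texels covered by only one input keep that input's color. In the
#' overlap region a minimum s-t cut over the 4-neighbor texel graph
#' (restricted within charts) decides the source per texel: neighbor
#' edges carry the color-mismatch capacity
#' `||I_A(p) - I_B(p)|| + ||I_A(q) - I_B(q)||`, texels adjacent to the
#' exclusive regions are hard-linked to the corresponding terminal, and
#' every overlap texel gets terminal capacities `w * (1 + normal_dot)`
#' from the facing maps (an order-preserving non-negative shift of the
#' printed costs) so front-facing texture is preferred.
#'
#' @param tex_a,tex_b `texture_atlas` objects on the same layout.
#' @param layout the shared `atlas_layout`.
#' @param w weight of the normal-dot terminal capacities.
#' @return a stitched `texture_atlas`; `source_id` records the winning
#'   input per texel.
#' @export
stitch_pair <- function(tex_a, tex_b, layout, w = 1) {
  if (tex_a$resolution != tex_b$resolution ||
      tex_a$resolution != layout$resolution)
    stop("texture/layout size mismatch")
  res <- tex_a$resolution
  U <- tex_a$covered & tex_b$covered
  onlyA <- tex_a$covered & !tex_b$covered
  onlyB <- tex_b$covered & !tex_a$covered
  out <- tex_a
  out$covered <- tex_a$covered | tex_b$covered
  out$pose_cost <- min(tex_a$pose_cost, tex_b$pose_cost, na.rm = TRUE)
  take <- function(m, from, sel) { m[sel] <- from[sel]; m }
  # exclusive regions
  for (d in 1:3)
    out$color[, , d] <- take(out$color[, , d], tex_b$color[, , d], onlyB)
  out$normal_dot <- take(out$normal_dot, tex_b$normal_dot, onlyB)
  out$source_id <- take(out$source_id, tex_b$source_id, onlyB)
  if (!any(U)) return(out)

  iu <- which(U)
  nid <- matrix(0L, res, res)
  nid[iu] <- seq_along(iu)
  n <- length(iu)
  rr <- ((iu - 1L) %% res) + 1L
  cc <- ((iu - 1L) %/% res) + 1L
  cid <- layout$chart_id[iu]
  cdiff <- sqrt((tex_a$color[, , 1] - tex_b$color[, , 1])^2 +
                (tex_a$color[, , 2] - tex_b$color[, , 2])^2 +
                (tex_a$color[, , 3] - tex_b$color[, , 3])^2)
  BIG <- 1e6
  # neighbor edges within U, same chart (right and down to avoid dupes)
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (off in list(c(1L, 0L), c(0L, 1L))) {
    r2 <- rr + off[1]; c2 <- cc + off[2]
    okn <- r2 >= 1 & r2 <= res & c2 >= 1 & c2 <= res
    j <- (c2[okn] - 1L) * res + r2[okn]
    i0 <- iu[okn]
    both <- nid[j] > 0 & layout$chart_id[j] == cid[okn]
    ef <- c(ef, nid[i0[both]])
    et <- c(et, nid[j[both]])
    ew <- c(ew, cdiff[i0[both]] + cdiff[j[both]])
  }
  # terminal capacities: assigning p away from a texture severs that
  # texture's terminal link, so the capacity grows with how frontal the
  # texture is there (normal_dot stores the facing measure -ray.normal)
  capS <- w * (1 + tex_a$normal_dot[iu])
  capT <- w * (1 + tex_b$normal_dot[iu])
  adjacent_to <- function(region) {
    hit <- logical(n)
    for (off in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      r2 <- rr + off[1]; c2 <- cc + off[2]
      okn <- r2 >= 1 & r2 <= res & c2 >= 1 & c2 <= res
      j <- (c2 - 1L) * res + r2
      hit[okn] <- hit[okn] | region[j[okn]]
    }
    hit
  }
  capS[adjacent_to(onlyA)] <- BIG
  capT[adjacent_to(onlyB)] <- BIG
  S <- n + 1L; T <- n + 2L
  edges <- rbind(cbind(S, seq_len(n)), cbind(seq_len(n), T), cbind(ef, et))
  caps <- c(capS, capT, ew)
  keep <- caps > 0
  g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < T) g <- igraph::add_vertices(g, T - igraph::vcount(g))
  cut <- igraph::min_cut(g, source = S, target = T,
                         capacity = caps[keep], value.only = FALSE)
  sideA <- logical(n)
  p1 <- as.integer(cut$partition1)
  if (S %in% p1) sideA[p1[p1 <= n]] <- TRUE
  else sideA[as.integer(cut$partition2)[as.integer(cut$partition2) <= n]] <- TRUE
  fromB <- iu[!sideA]
  for (d in 1:3)
    out$color[, , d] <- take(out$color[, , d], tex_b$color[, , d], fromB)
  out$normal_dot <- take(out$normal_dot, tex_b$normal_dot, fromB)
  out$source_id <- take(out$source_id, tex_b$source_id, fromB)
  out
}

#' Merge any number of textures into one atlas
#'
#' Iterative pairwise stitching with [stitch_pair()]. The merge order is
#' deterministic: textures are sorted by decreasing covered-texel count,
#' ties broken by ascending pose cost and then by list name.
#'
#' @param textures non-empty list of `texture_atlas` objects.
#' @param layout the shared `atlas_layout`.
#' @param w terminal-capacity weight passed to [stitch_pair()].
#' @return the merged `texture_atlas`; its covered set is the union of
#'   the inputs' covered sets.
#' @export
merge_all <- function(textures, layout, w = 1) {
  if (length(textures) == 0) stop("no textures to merge")
  nm <- names(textures)
  if (is.null(nm)) nm <- sprintf("%03d", seq_along(textures))
  covn <- vapply(textures, function(t) sum(t$covered), 0)
  pc <- vapply(textures, function(t)
    if (is.na(t$pose_cost)) Inf else t$pose_cost, 0)
  ord <- order(-covn, pc, nm)
  acc <- textures[[ord[1]]]
  for (i in ord[-1]) acc <- stitch_pair(acc, textures[[i]], layout, w)
  acc
}
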