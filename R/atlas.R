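#' Segment a mesh into near-flat charts
#'
#' Greedy region growing over face adjacency: starting from the lowest
#' unassigned face id, a neighboring face joins the chart iff its normal
#' deviates from the chart seed's normal by at most the cone angle.
#' Every face is assigned to exactly one chart.
#'
#' @param mesh an edge-manifold [triangle_mesh()].
#' @param max_normal_cone_deg cone half-angle in degrees (default 35).
#' @return list of integer vectors of face ids (the charts).
#' @export
segment_charts <- function(mesh, max_normal_cone_deg = 35) {
  if (!mesh_is_edge_manifold(mesh))
    stop("mesh is not edge-manifold")
  nf <- nrow(mesh$faces)
  adj <- face_adjacency(mesh)
  cosmax <- cos(max_normal_cone_deg * pi / 180)
  chart <- integer(nf)
  charts <- list()
  for (seed in seq_len(nf)) {
    if (chart[seed] != 0) next
    id <- length(charts) + 1L
    sn <- mesh$face_normals[seed, ]
    members <- integer(0)
    queue <- seed
    chart[seed] <- id
    while (length(queue)) {
      f <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, f)
      for (nb in adj[[f]]) {
        if (chart[nb] == 0 && sum(mesh$face_normals[nb, ] * sn) >= cosmax) {
          chart[nb] <- id
          queue <- c(queue, nb)
        }
      }
    }
    charts[[id]] <- sort(members)
  }
  charts
}

# faces sharing an edge; list indexed by face id
face_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(nrow(f)), 3)
  groups <- split(fid, key)
  adj <- vector("list", nrow(f))
  for (g in groups) {
    if (length(g) == 2) {
      adj[[g[1]]] <- c(adj[[g[1]]], g[2])
      adj[[g[2]]] <- c(adj[[g[2]]], g[1])
    }
  }
  adj
}

#' Flatten charts and pack them into a texture atlas
#'
#' Each chart is flattened by orthogonal projection onto the plane of its
#' area-weighted average normal (charts are near-flat by construction, so
#' the distortion is bounded by the normal cone). Charts that fold over
#' under projection (a projected triangle flips orientation) are split in
#' two and re-flattened. Flattened charts are shelf-packed by decreasing
#' height into `[0,1]^2` with a gutter of at least 2 texels, and the
#' atlas-to-surface map is filled by rasterizing the UV triangles.
#'
#' @param mesh a [triangle_mesh()].
#' @param charts list of face-id vectors from [segment_charts()].
#' @param resolution atlas size in texels (square).
#' @param gutter_texels minimum spacing between charts [texels].
#' @param max_splits maximum recursive fold-over splits per chart.
#' @return an `atlas_layout`: list with `charts` (face ids, per-corner
#'   uv), `resolution`, `face` (texel -> face id matrix, 0 = empty),
#'   `bary` (3 matrices of barycentric coordinates), `chart_id`
#'   (texel -> chart index), and `uv` stored per face corner.
#' @export
flatten_and_pack <- function(mesh, charts, resolution = 512,
                             gutter_texels = 2, max_splits = 10) {
  # recursively flatten, splitting charts that fold over
  flat <- list()
  queue <- lapply(charts, function(f) list(faces = f, depth = 0))
  adj <- NULL
  while (length(queue)) {
    it <- queue[[1]]
    queue <- queue[-1]
    fl <- flatten_chart(mesh, it$faces)
    if (!is.null(fl)) {
      flat[[length(flat) + 1]] <- fl
      next
    }
    if (it$depth >= max_splits)
      stop("chart could not be flattened after ", max_splits, " splits")
    halves <- split_chart(mesh, it$faces)
    queue <- c(queue, list(list(faces = halves[[1]], depth = it$depth + 1),
                           list(faces = halves[[2]], depth = it$depth + 1)))
  }
  # global mm-to-uv scale, then shelf packing by decreasing height
  g <- gutter_texels / resolution
  scale_for <- function(s) {
    # returns packed height (in uv units) at trial scale s, or Inf
    ws <- vapply(flat, function(f) diff(range(f$xy[, 1])), 0) * s + g
    hs <- vapply(flat, function(f) diff(range(f$xy[, 2])), 0) * s + g
    if (any(ws > 1)) return(Inf)
    ord <- order(-hs)
    x <- g; y <- g; shelf <- 0
    for (i in ord) {
      if (x + ws[i] > 1) { x <- g; y <- y + shelf; shelf <- 0 }
      x <- x + ws[i]
      shelf <- max(shelf, hs[i])
    }
    y + shelf + g
  }
  lo <- 0
  hi <- 1 / max(vapply(flat, function(f) max(diff(range(f$xy[, 1])),
                                             diff(range(f$xy[, 2]))), 0))
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (scale_for(mid) <= 1) lo <- mid else hi <- mid
  }
  s <- lo * 0.999
  if (s <= 0) stop("charts do not fit the atlas resolution")
  ws <- vapply(flat, function(f) diff(range(f$xy[, 1])), 0) * s + g
  hs <- vapply(flat, function(f) diff(range(f$xy[, 2])), 0) * s + g
  ord <- order(-hs)
  x <- g; y <- g; shelf <- 0
  for (i in ord) {
    if (x + ws[i] > 1) { x <- g; y <- y + shelf; shelf <- 0 }
    f <- flat[[i]]
    off <- c(x - min(f$xy[, 1]) * s, y - min(f$xy[, 2]) * s)
    flat[[i]]$uv <- sweep(f$xy * s, 2, off, `+`)
    x <- x + ws[i]
    shelf <- max(shelf, hs[i])
  }
  # rasterize uv triangles into the texel grid
  out_charts <- list()
  nface <- nrow(mesh$faces)
  all_uv <- matrix(0, 0, 2)
  all_tri <- matrix(0L, 0, 3)
  all_fid <- integer(0)
  all_cid <- integer(0)
  for (ci in seq_along(flat)) {
    f <- flat[[ci]]
    base <- nrow(all_uv)
    all_uv <- rbind(all_uv, f$uv)
    all_tri <- rbind(all_tri, f$corner_idx + base)
    all_fid <- c(all_fid, f$faces)
    all_cid <- c(all_cid, rep(ci, length(f$faces)))
    out_charts[[ci]] <- list(face_ids = f$faces, uv = f$uv,
                             seed_face = f$faces[1])
  }
  ras <- rasterize_uv_cpp(all_uv, all_tri - 1L, all_fid, resolution)
  chart_of_face <- integer(nface)
  chart_of_face[all_fid] <- all_cid
  chart_id <- matrix(0L, resolution, resolution)
  cov <- ras$face > 0
  chart_id[cov] <- chart_of_face[ras$face[cov]]
  structure(list(charts = out_charts, resolution = resolution,
                 face = ras$face,
                 bary = list(ras$b0, ras$b1, ras$b2),
                 chart_id = chart_id,
                 face_uv = list(uv = all_uv, tri = all_tri, fid = all_fid)),
            class = "atlas_layout")
}

#' @export
print.atlas_layout <- function(x, ...) {
  cat(sprintf("<atlas_layout> %d charts, %d x %d texels, %.1f%% covered\n",
              length(x$charts), x$resolution, x$resolution,
              100 * mean(x$face > 0)))
  invisible(x)
}

# orthogonal projection of one chart onto its average-normal plane;
# NULL if any projected triangle degenerates or flips
flatten_chart <- function(mesh, faces) {
  fn <- mesh$face_normals[faces, , drop = FALSE]
  ar <- face_areas(mesh)[faces]
  n <- colSums(fn * ar)
  if (sum(n^2) < 1e-20) return(NULL)
  n <- n / sqrt(sum(n^2))
  e1 <- cross3(n, c(0, 0, 1))
  if (sum(e1^2) < 1e-12) e1 <- cross3(n, c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(n, e1)
  vid <- unique(as.vector(mesh$faces[faces, , drop = FALSE]))
  vmap <- integer(nrow(mesh$vertices))
  vmap[vid] <- seq_along(vid)
  p <- mesh$vertices[vid, , drop = FALSE]
  xy <- cbind(p %*% e1, p %*% e2)
  tri <- matrix(vmap[mesh$faces[faces, , drop = FALSE]], ncol = 3)
  # orientation check: projected signed area must not flip
  a <- xy[tri[, 1], , drop = FALSE]
  b <- xy[tri[, 2], , drop = FALSE]
  cc <- xy[tri[, 3], , drop = FALSE]
  s2 <- (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
        (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  # 3D orientation relative to the projection normal
  s3 <- rowSums(face_normals(mesh$vertices,
                             mesh$faces[faces, , drop = FALSE]) *
                  matrix(n, length(faces), 3, byrow = TRUE))
  if (any(sign(s2) * sign(s3) < 0) || any(s2 == 0)) return(NULL)
  list(faces = faces, xy = xy, corner_idx = tri)
}

# split a chart into two halves by BFS order from its seed face
split_chart <- function(mesh, faces) {
  adj <- face_adjacency(mesh)
  inset <- logical(nrow(mesh$faces))
  inset[faces] <- TRUE
  visited <- logical(nrow(mesh$faces))
  order_out <- integer(0)
  queue <- faces[1]
  visited[faces[1]] <- TRUE
  while (length(queue)) {
    f <- queue[[1]]
    queue <- queue[-1]
    order_out <- c(order_out, f)
    for (nb in adj[[f]]) {
      if (inset[nb] && !visited[nb]) {
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  # disconnected remainder goes to the second half
  rest <- setdiff(faces, order_out)
  h <- ceiling(length(order_out) / 2)
  list(sort(order_out[seq_len(h)]),
       sort(c(order_out[-seq_len(h)], rest)))
}
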