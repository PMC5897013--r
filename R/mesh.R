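#' Triangle mesh
#'
#' Container for a triangulated surface in mm units: an n x 3 vertex
#' matrix, an m x 3 face index matrix (1-based), unit face and vertex
#' normals, and the mass center (unweighted vertex mean) which serves as
#' the origin of the spherical camera system.
#'
#' @param vertices n x 3 numeric matrix [mm].
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @param uv optional n x 2 matrix of texture coordinates in `[0,1]^2`.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, uv = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (nrow(faces) == 0 || nrow(vertices) == 0) stop("empty mesh")
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face index out of range")
  fn <- face_normals(vertices, faces)
  structure(list(vertices = vertices, faces = faces,
                 face_normals = fn,
                 vertex_normals = vertex_normals(vertices, faces, fn),
                 mass_center = colMeans(vertices), uv = uv),
            class = "triangle_mesh")
}

face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

vertex_normals <- function(vertices, faces, fn) {
  vn <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      vn[, d] <- vn[, d] +
        tabulate2(faces[, k], fn[, d], nrow(vertices))
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$uv)) ", with UVs" else ""))
  invisible(x)
}

face_areas <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - a
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

mesh_surface_area <- function(mesh) sum(face_areas(mesh))

#' Icosphere mesh
#'
#' Unit sphere triangulated by recursive icosahedron subdivision;
#' `10 * 4^subdiv + 2` vertices.
#'
#' @param subdiv number of subdivision levels (0 = icosahedron).
#' @param radius sphere radius.
#' @return a [triangle_mesh()].
#' @export
icosphere <- function(subdiv = 2, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1
      vlist[[length(vlist) + 1]] <<- m
      mid_cache[[key]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  triangle_mesh(v * radius, f)
}

#' Read a mesh from an OBJ or PLY file
#'
#' OBJ: `v`, `vt` and `f` records (`f v`, `f v/vt`, `f v/vt/vn` or
#' `f v//vn`); polygonal faces are fan-triangulated. PLY: ASCII format
#' with vertex x/y/z properties and a face vertex list.
#'
#' @param path file path; format chosen by extension.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") read_obj(path)
  else if (ext == "ply") read_ply(path)
  else stop("unsupported mesh format: ", ext)
}

read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vs <- ln[startsWith(ln, "v ")]
  vts <- ln[startsWith(ln, "vt ")]
  fs <- ln[startsWith(ln, "f ")]
  parse_num <- function(lines, take) {
    t(vapply(strsplit(trimws(lines), "\\s+"),
             function(x) as.numeric(x[2:(1 + take)]), numeric(take)))
  }
  v <- parse_num(vs, 3)
  uv <- if (length(vts)) parse_num(vts, 2) else NULL
  ftri <- list()
  fuv <- list()
  for (fl in fs) {
    toks <- strsplit(trimws(fl), "\\s+")[[1]][-1]
    vi <- as.integer(vapply(strsplit(toks, "/"), `[`, character(1), 1))
    ti <- vapply(strsplit(toks, "/"), function(x)
      if (length(x) >= 2 && nzchar(x[2])) x[2] else NA_character_,
      character(1))
    ti <- suppressWarnings(as.integer(ti))
    for (k in seq_len(length(vi) - 2)) {
      ftri[[length(ftri) + 1]] <- vi[c(1, k + 1, k + 2)]
      fuv[[length(fuv) + 1]] <- ti[c(1, k + 1, k + 2)]
    }
  }
  faces <- do.call(rbind, ftri)
  mesh <- triangle_mesh(v, faces)
  if (!is.null(uv) && !anyNA(fuv[[1]])) {
    # per-corner uvs: keep as vertex uv when the obj shares indices
    fuv <- do.call(rbind, fuv)
    vuv <- matrix(NA_real_, nrow(v), 2)
    vuv[as.vector(faces), ] <- uv[as.vector(fuv), , drop = FALSE]
    if (!anyNA(vuv)) mesh$uv <- vuv
  }
  mesh
}

read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (ln[1] != "ply" || !any(grepl("format ascii", ln)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "", ln[grepl("^element vertex", ln)]))
  nf <- as.integer(sub("element face ", "", ln[grepl("^element face", ln)]))
  start <- which(ln == "end_header") + 1
  vlines <- ln[start:(start + nv - 1)]
  flines <- ln[(start + nv):(start + nv + nf - 1)]
  v <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                function(x) as.numeric(x[1:3]), numeric(3)))
  f <- t(vapply(strsplit(trimws(flines), "\\s+"),
                function(x) as.integer(x[2:4]) + 1L, integer(3)))
  triangle_mesh(v, f)
}

#' Write a mesh to OBJ (with optional UVs and material) or ASCII PLY
#'
#' @param mesh a [triangle_mesh()]; if `mesh$uv` is present, `vt` records
#'   and `f v/vt` faces are written.
#' @param path output path; format chosen by extension.
#' @param mtl_path,texture_png optional material file and texture image
#'   referenced from the OBJ.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, mtl_path = NULL, texture_png = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    out <- character(0)
    if (!is.null(mtl_path)) {
      out <- c(out, paste("mtllib", basename(mtl_path)))
      mtl <- c("newmtl textured", "Ka 1 1 1", "Kd 1 1 1",
               if (!is.null(texture_png)) paste("map_Kd", basename(texture_png)))
      writeLines(mtl, mtl_path)
    }
    out <- c(out, sprintf("v %.8g %.8g %.8g", mesh$vertices[, 1],
                          mesh$vertices[, 2], mesh$vertices[, 3]))
    if (!is.null(mesh$uv)) {
      out <- c(out, sprintf("vt %.8g %.8g", mesh$uv[, 1], mesh$uv[, 2]))
      if (!is.null(mtl_path)) out <- c(out, "usemtl textured")
      out <- c(out, sprintf("f %d/%d %d/%d %d/%d",
                            mesh$faces[, 1], mesh$faces[, 1],
                            mesh$faces[, 2], mesh$faces[, 2],
                            mesh$faces[, 3], mesh$faces[, 3]))
    } else {
      out <- c(out, sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                            mesh$faces[, 3]))
    }
    writeLines(out, path)
  } else if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(mesh$vertices)),
             "property float x", "property float y", "property float z",
             paste("element face", nrow(mesh$faces)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(c(hdr,
                 sprintf("%.8g %.8g %.8g", mesh$vertices[, 1],
                         mesh$vertices[, 2], mesh$vertices[, 3]),
                 sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                         mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)),
               path)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

# edge-manifold: no edge shared by more than two faces (boundary edges
# with one face are fine); watertight additionally requires exactly two
mesh_is_edge_manifold <- function(mesh) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
             mesh$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) <= 2)
}

mesh_is_watertight <- function(mesh) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
             mesh$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}
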