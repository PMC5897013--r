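# Independent brute-force oracles used to validate the fast paths.

# boundary pixels by exhaustive neighbor scan
boundary_oracle <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- NULL
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!img[i, j]) next
    nb <- c(if (i > 1) img[i - 1, j] else FALSE,
            if (i < h) img[i + 1, j] else FALSE,
            if (j > 1) img[i, j - 1] else FALSE,
            if (j < w) img[i, j + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(i, j))
  }
  out
}

# exact distance-to-boundary by O(N * |B|) search
distance_field_oracle <- function(img) {
  b <- boundary_oracle(img)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (j in seq_len(w)) for (i in seq_len(h))
    out[i, j] <- sqrt(min((b[, 1] - i)^2 + (b[, 2] - j)^2))
  out
}

# bilinear sample with border clamping, coordinates in pixel units
sample_bilinear_oracle <- function(D, row, col) {
  h <- nrow(D); w <- ncol(D)
  row <- min(max(row, 1), h); col <- min(max(col, 1), w)
  i0 <- min(floor(row), h - 1); j0 <- min(floor(col), w - 1)
  fr <- row - i0; fc <- col - j0
  (1 - fr) * ((1 - fc) * D[i0, j0] + fc * D[i0, j0 + 1]) +
    fr * ((1 - fc) * D[i0 + 1, j0] + fc * D[i0 + 1, j0 + 1])
}

# exhaustive 1-degree rotation search (independent R loop)
alpha_search_oracle <- function(D, g_t, bpts, g_r) {
  best <- Inf; best_a <- 0
  sx <- bpts[, 2] - g_r[2]
  sy <- g_r[1] - bpts[, 1]
  for (a in 0:359) {
    ca <- cos(a * pi / 180); sa <- sin(a * pi / 180)
    rx <- ca * sx - sa * sy
    ry <- sa * sx + ca * sy
    acc <- 0
    for (k in seq_along(rx))
      acc <- acc + sample_bilinear_oracle(D, g_t[1] - ry[k], g_t[2] + rx[k])
    cost <- acc / length(rx)
    if (cost < best) { best <- cost; best_a <- a }
  }
  c(cost = best, alpha_deg = best_a)
}

# point-in-mesh by ray parity along +x (independent of the z-column
# voxelizer; jitters the ray to dodge edge hits)
inside_mesh_oracle <- function(points, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  apply(rbind(points), 1, function(p) {
    p <- p + c(0, 1.7e-6, 3.1e-6)
    hits <- 0
    for (t in seq_len(nrow(f))) {
      a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; cc <- v[f[t, 3], ]
      d1 <- (b[2] - a[2]) * (p[3] - a[3]) - (b[3] - a[3]) * (p[2] - a[2])
      d2 <- (cc[2] - b[2]) * (p[3] - b[3]) - (cc[3] - b[3]) * (p[2] - b[2])
      d3 <- (a[2] - cc[2]) * (p[3] - cc[3]) - (a[3] - cc[3]) * (p[2] - cc[2])
      if ((d1 < 0 || d2 < 0 || d3 < 0) && (d1 > 0 || d2 > 0 || d3 > 0)) next
      den <- d1 + d2 + d3
      if (den == 0) next
      x <- (d2 * a[1] + d3 * b[1] + d1 * cc[1]) / den
      if (x > p[1]) hits <- hits + 1
    }
    hits %% 2 == 1
  })
}

# pixel-center point-in-triangle coverage by half-plane inclusion
triangle_coverage_oracle <- function(u, v, width, height) {
  # u, v: length-3 projected corner coordinates (continuous pixel space)
  covered <- matrix(FALSE, height, width)
  for (i in seq_len(height)) for (j in seq_len(width)) {
    px <- j - 0.5; py <- i - 0.5
    e <- function(ax, ay, bx, by) (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    e0 <- e(u[1], v[1], u[2], v[2])
    e1 <- e(u[2], v[2], u[3], v[3])
    e2 <- e(u[3], v[3], u[1], v[1])
    covered[i, j] <- all(c(e0, e1, e2) > 0) || all(c(e0, e1, e2) < 0)
  }
  covered
}

# minimum labeling cost by exhaustive enumeration of the overlap region
# (labels: TRUE = keep texture A / source side)
mincut_oracle <- function(capS, capT, edges, ew) {
  n <- length(capS)
  best <- Inf
  for (m in 0:(2^n - 1)) {
    lab <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    cost <- sum(capT[lab]) + sum(capS[!lab])
    if (length(ew))
      cost <- cost + sum(ew[lab[edges[, 1]] != lab[edges[, 2]]])
    if (cost < best) best <- cost
  }
  best
}

# small deterministic fixtures shared across files
tiny_intr <- function() camera_intrinsics(116, 77, focal_px = 500)
small_mesh <- function(seed = 7) make_mesh("insectoid", 60, rng_seed = seed,
                                           subdiv = 3)
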