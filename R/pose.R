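#' Solver configuration for camera pose estimation
#'
#' Bundles the search hyperparameters of the three-stage solver. The
#' defaults follow the published settings: 2562 sphere directions,
#' candidate distances `r0 + {0, +-10, +-20, +-30}` mm, a 1-degree
#' rotation grid, gradient scales `s = (1e-4, 1e-4, 1e1, 1e-7, 1e-7,
#' 1e-7)`, central-difference offsets `h = 0.1 * 2*pi/360` for the five
#' angles and `10` mm for r, 1000 hill-climbing steps with proposals
#' from `[-0.1, 0.1]` mm in r and `[-0.01, 0.01]` rad in the angles, and
#' the acceptance threshold 0.7 px below which a photograph is used for
#' texturing.
#'
#' @param r0 approximate camera-specimen distance [mm].
#' @param n_sphere number of candidate directions; must be an icosphere
#'   count `10 * 4^k + 2` (12, 42, 162, 642, 2562, ...).
#' @param r_offsets candidate distance offsets added to `r0` [mm].
#' @param s per-dimension gradient scale (theta, phi, r, dx, dy, dz).
#' @param h_offsets central-difference offsets per dimension.
#' @param n_hill number of hill-climbing iterations.
#' @param hill_range_r,hill_range_angle half-widths of the uniform
#'   hill-climb proposals [mm, rad].
#' @param discard_threshold photographs with final cost at or above this
#'   value [px] are rejected.
#' @param render_width,render_height size of the matching renders [px].
#' @param max_gd_iters,gd_tolerance gradient-descent stopping rule
#'   (iteration cap; minimum relative cost improvement).
#' @param n_starts number of top-ranked coarse candidates refined
#'   independently; the best final cost wins (1 = single chain).
#' @param rank_boundary_cap boundary-pixel subsample cap used only while
#'   ranking the coarse candidates (0 = exact; the refinement stages and
#'   all public metrics always use full boundaries).
#' @param rng_seed seed for the stochastic hill-climbing stage.
#' @return an object of class `search_config`.
#' @export
search_config <- function(r0,
                          n_sphere = 2562,
                          r_offsets = c(0, -10, 10, -20, 20, -30, 30),
                          s = c(1e-4, 1e-4, 1e1, 1e-7, 1e-7, 1e-7),
                          h_offsets = c(0.1 * 2 * pi / 360,
                                        0.1 * 2 * pi / 360, 10,
                                        0.1 * 2 * pi / 360,
                                        0.1 * 2 * pi / 360,
                                        0.1 * 2 * pi / 360),
                          n_hill = 1000,
                          hill_range_r = 0.1,
                          hill_range_angle = 1e-2,
                          discard_threshold = 0.7,
                          render_width = 462, render_height = 306,
                          max_gd_iters = 50, gd_tolerance = 1e-4,
                          n_starts = 5, rank_boundary_cap = 200,
                          rng_seed = 1L) {
  stopifnot(r0 > 0, discard_threshold > 0, n_hill >= 0, max_gd_iters >= 0,
            n_starts >= 1)
  structure(list(r0 = r0, n_sphere = n_sphere, r_offsets = r_offsets,
                 s = s, h_offsets = h_offsets, n_hill = n_hill,
                 hill_range_r = hill_range_r,
                 hill_range_angle = hill_range_angle,
                 discard_threshold = discard_threshold,
                 render_width = as.integer(render_width),
                 render_height = as.integer(render_height),
                 max_gd_iters = max_gd_iters, gd_tolerance = gd_tolerance,
                 n_starts = n_starts,
                 rank_boundary_cap = rank_boundary_cap,
                 rng_seed = rng_seed),
            class = "search_config")
}

#' Near-uniform unit sphere directions
#'
#' Vertices of a subdivided icosahedron (`10 * 4^k + 2` points), the
#' candidate camera directions of the coarse search; azimuth/altitude
#' extracted per the spherical convention of the camera frame
#' (`pos = R_y(theta) R_z(phi) (r,0,0)'`).
#'
#' @param n direction count; one of 12, 42, 162, 642, 2562, 10242, ...
#' @return n x 2 matrix with columns `theta`, `phi` [rad].
#' @export
sphere_directions <- function(n) {
  if (n < 12) stop("need at least 12 directions")
  k <- log((n - 2) / 10, base = 4)
  if (abs(k - round(k)) > 1e-9)
    stop("n must be an icosphere count 10 * 4^k + 2 (12, 42, 162, 642, 2562, ...)")
  v <- icosphere(round(k))$vertices
  cbind(theta = atan2(-v[, 3], v[, 1]), phi = asin(pmin(1, pmax(-1, v[, 2]))))
}

#' Precompute candidate silhouettes for the coarse search
#'
#' Renders the mesh from every (direction, distance) candidate with zero
#' local rotations and stores boundary pixels and mass centers. The cache
#' depends only on mesh, intrinsics and configuration, so it is shared
#' across all photographs with the same approximate distance.
#'
#' @inheritParams estimate_camera_pose
#' @return an object of class `pose_search_cache`.
#' @export
pose_search_cache <- function(mesh, intr, cfg) {
  dirs <- sphere_directions(cfg$n_sphere)
  rs <- cfg$r0 + cfg$r_offsets
  rs <- rs[rs > 0]
  nc <- nrow(dirs) * length(rs)
  cand <- matrix(0, nc, 3)
  bpts <- vector("list", nc)
  grs <- matrix(NA_real_, nc, 2)
  i <- 0L
  for (l in seq_along(rs)) {
    for (k in seq_len(nrow(dirs))) {
      i <- i + 1L
      cand[i, ] <- c(dirs[k, 1], dirs[k, 2], rs[l])
      sil <- render_silhouette(
        mesh, camera_pose(dirs[k, 1], dirs[k, 2], rs[l]), intr)
      if (any(sil)) {
        bpts[[i]] <- matrix(as.numeric(extract_boundary(sil)), ncol = 2)
        grs[i, ] <- foreground_centroid(sil)
      }
    }
  }
  structure(list(candidates = cand, bpts = bpts, grs = grs, intr = intr),
            class = "pose_search_cache")
}

#' Coarse exhaustive search over camera position candidates
#'
#' Evaluates the rotation/translation-compensated matching cost for every
#' (direction, distance) candidate and converts the winning alignment
#' into initial local rotations. The photograph's distance field is
#' computed once and reused for all candidates.
#'
#' @inheritParams estimate_camera_pose
#' @param cache optional [pose_search_cache()]; built on the fly if
#'   missing.
#' @param photo_dt optional precomputed [distance_field()] of `photo`.
#' @return list with `pose` (the initial six-parameter estimate),
#'   `aligned_cost` [px] and `alpha` [rad].
#' @export
initial_search <- function(photo, mesh, intr, cfg, cache = NULL,
                           photo_dt = NULL, n_best = 1) {
  if (!any(photo)) stop("empty photograph silhouette")
  if (is.null(cache)) cache <- pose_search_cache(mesh, intr, cfg)
  if (is.null(photo_dt)) photo_dt <- distance_field(photo)
  g_t <- foreground_centroid(photo)
  live <- !vapply(cache$bpts, is.null, logical(1))
  if (!any(live)) stop("pose estimation failed: all candidate renders empty")
  res <- alpha_search_batch_cpp(photo_dt, g_t, cache$bpts, cache$grs,
                                max_pts = cfg$rank_boundary_cap,
                                n_keep = n_best)
  ord <- order(res[, 1])[seq_len(min(n_best, sum(live)))]
  mk <- function(i) {
    alpha <- res[i, 2] * pi / 180
    align <- list(alpha = alpha, g_t = g_t, g_r = cache$grs[i, ],
                  g_r_rot = rotate_about_center(cache$grs[i, ], alpha,
                                                c(intr$height, intr$width)))
    d0 <- rotation_from_alignment(align, intr)
    cnd <- cache$candidates[i, ]
    list(pose = camera_pose(cnd[1], cnd[2], cnd[3], d0[1], d0[2], d0[3]),
         aligned_cost = res[i, 1], alpha = alpha)
  }
  out <- mk(ord[1])
  out$ranked <- lapply(ord, mk)
  out
}

# Eq-3 cost of a full six-parameter pose against a precomputed photo
# distance field; Inf when the render is empty. Fused render/boundary/
# average in C++ (no buffers cross into R).
pose_cost <- function(v, photo_dt, mesh, intr) {
  if (v[3] <= 0) return(Inf)
  pose <- vector_to_pose(v)
  frame <- camera_frame(pose)
  vc <- world_to_camera(mesh$vertices, frame, mesh$mass_center)
  cost <- silhouette_cost_cpp(vc, mesh$faces - 1L, intr$focal_px,
                              intr$width, intr$height, photo_dt)
  if (cost < 0) Inf else cost
}

#' Gradient-descent refinement of a camera pose
#'
#' Minimizes the boundary-distance cost with central-difference gradients
#' (two renders per dimension) scaled per dimension, and a backtracking
#' line search over step sizes `1, 1/2, ..., 2^-10` that accepts the
#' first strict improvement. Stops at `max_gd_iters`, when no step
#' improves, or when the relative improvement falls below
#' `gd_tolerance`. Never returns a worse pose than the input.
#'
#' @inheritParams estimate_camera_pose
#' @param c0 starting [camera_pose()].
#' @param photo_dt optional precomputed [distance_field()] of `photo`.
#' @return list with `pose` and `cost` [px].
#' @export
refine_gradient_descent <- function(c0, photo, mesh, intr, cfg,
                                    photo_dt = NULL) {
  if (is.null(photo_dt)) photo_dt <- distance_field(photo)
  v <- pose_to_vector(c0)
  cur <- pose_cost(v, photo_dt, mesh, intr)
  for (it in seq_len(cfg$max_gd_iters)) {
    if (!is.finite(cur) || cur == 0) break
    moved <- FALSE
    converged <- FALSE
    mult <- 1
    # the cost surface is a staircase at pixel granularity; when the
    # base offsets fall inside one flat step the difference quotient is
    # pure noise, so widen the stencil until a descent step is found
    while (mult <= 32 && !moved) {
      g <- numeric(6)
      for (k in 1:6) {
        hk <- cfg$h_offsets[k] * mult
        vp <- v; vp[k] <- vp[k] + hk
        vm <- v; vm[k] <- vm[k] - hk
        cp <- pose_cost(vp, photo_dt, mesh, intr)
        cm <- pose_cost(vm, photo_dt, mesh, intr)
        g[k] <- if (is.finite(cp) && is.finite(cm)) (cp - cm) / (2 * hk) else 0
      }
      if (any(g != 0)) {
        step <- cfg$s * g
        for (h in 2^(12:-10)) {
          vn <- v - h * step
          cn <- pose_cost(vn, photo_dt, mesh, intr)
          if (cn < cur) {
            converged <- (cur - cn) / cur < cfg$gd_tolerance
            v <- vn
            cur <- cn
            moved <- TRUE
            break
          }
        }
      }
      mult <- mult * 2
    }
    if (!moved || converged) break
  }
  list(pose = vector_to_pose(v), cost = cur)
}

#' Hill-climbing refinement of a camera pose
#'
#' Stochastic local search: at each step one of the six dimensions is
#' chosen at random and perturbed by a uniform offset (`[-0.1, 0.1]` mm
#' for r, `[-0.01, 0.01]` rad for the angles); the proposal is accepted
#' only if the cost strictly decreases. Deterministic for a fixed
#' `cfg$rng_seed`.
#'
#' @inheritParams refine_gradient_descent
#' @param c0 starting [camera_pose()] (typically the gradient-descent
#'   result).
#' @return a `pose_estimate`: list with `pose`, `cost` [px], `accepted`
#'   (cost below the discard threshold) and `trace`.
#' @export
refine_hill_climb <- function(c0, photo, mesh, intr, cfg, photo_dt = NULL) {
  if (is.null(photo_dt)) photo_dt <- distance_field(photo)
  if (!is.null(cfg$rng_seed)) {
    restore <- preserve_rng()
    on.exit(restore())
    set.seed(cfg$rng_seed)
  }
  v <- pose_to_vector(c0)
  cur <- pose_cost(v, photo_dt, mesh, intr)
  ranges <- c(cfg$hill_range_angle, cfg$hill_range_angle, cfg$hill_range_r,
              cfg$hill_range_angle, cfg$hill_range_angle,
              cfg$hill_range_angle)
  for (it in seq_len(cfg$n_hill)) {
    k <- sample.int(6, 1)
    vn <- v
    vn[k] <- vn[k] + runif(1, -ranges[k], ranges[k])
    if (vn[3] <= 0) next
    cn <- pose_cost(vn, photo_dt, mesh, intr)
    if (cn < cur) { v <- vn; cur <- cn }
  }
  pose_estimate(vector_to_pose(v), cur, cfg)
}

# snapshot the global RNG state; returns a restorer so seeded stages do
# not disturb the caller's random stream
preserve_rng <- function() {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  function() {
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

pose_estimate <- function(pose, cost, cfg, trace = NULL) {
  structure(list(pose = pose, cost = cost,
                 accepted = is.finite(cost) && cost < cfg$discard_threshold,
                 trace = trace),
            class = "pose_estimate")
}

#' @export
print.pose_estimate <- function(x, ...) {
  cat(sprintf("<pose_estimate> cost=%.4f px, %s\n", x$cost,
              if (x$accepted) "accepted" else "rejected"))
  print(x$pose)
  invisible(x)
}

#' Estimate the camera pose of a photograph by silhouette matching
#'
#' The full three-stage solver: (i) coarse exhaustive search over sphere
#' directions and candidate distances with 2D rotation/translation
#' compensation, (ii) gradient-descent refinement, (iii) hill climbing.
#' Photographs whose final cost is not below the discard threshold
#' (default 0.7 px) are flagged `accepted = FALSE` and excluded from
#' texturing.
#'
#' @param photo binarized photograph (logical matrix) at the render size.
#' @param mesh the specimen [triangle_mesh()].
#' @param intr [camera_intrinsics()] of the (reduced) photographs.
#' @param cfg a [search_config()].
#' @param cache optional [pose_search_cache()] shared across photographs.
#' @return a `pose_estimate` with per-stage costs in `$trace`.
#' @export
estimate_camera_pose <- function(photo, mesh, intr, cfg, cache = NULL) {
  if (!any(photo)) stop("empty photograph silhouette")
  photo_dt <- distance_field(photo)
  ini <- initial_search(photo, mesh, intr, cfg, cache, photo_dt,
                        n_best = cfg$n_starts)
  best <- NULL
  scfg <- cfg
  for (s in seq_along(ini$ranked)) {
    start <- ini$ranked[[s]]
    cost0 <- pose_cost(pose_to_vector(start$pose), photo_dt, mesh, intr)
    scfg$rng_seed <- if (is.null(cfg$rng_seed)) NULL else cfg$rng_seed + s - 1L
    gd <- refine_gradient_descent(start$pose, photo, mesh, intr, scfg,
                                  photo_dt)
    hc <- refine_hill_climb(gd$pose, photo, mesh, intr, scfg, photo_dt)
    hc$trace <- c(initial = cost0, gradient_descent = gd$cost,
                  hill_climb = hc$cost)
    if (is.null(best) || hc$cost < best$cost) best <- hc
  }
  best
}
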