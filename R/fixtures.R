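#' Synthetic specimen meshes for evaluation
#'
#' Generates watertight, rotationally asymmetric meshes emulating the
#' silhouette complexity of real specimens: a deformed icosphere whose
#' radial field carries seeded random protrusions. `insectoid` has many
#' narrow appendage-like lobes (most silhouette detail, the default for
#' camera-recovery experiments), `blob` broad smooth humps, and
#' `orchidoid` a few wide petal-like lobes. Pose recovery from
#' silhouettes requires that no two viewing directions produce the same
#' outline; the protrusions guarantee that (smooth near-spherical bodies
#' are the documented failure mode of silhouette matching).
#'
#' @param kind `"insectoid"`, `"blob"` or `"orchidoid"`.
#' @param scale_mm bounding-box diagonal of the mesh [mm].
#' @param rng_seed seed; the same seed reproduces the same vertex array.
#' @param subdiv icosphere subdivision level of the base mesh.
#' @return a [triangle_mesh()] centered on its mass center, with an
#'   `inside` attribute: a vectorized function testing point membership
#'   in the enclosed solid (the generator's own radial field, usable as
#'   an analytic oracle).
#' @export
make_mesh <- function(kind = c("insectoid", "blob", "orchidoid"),
                      scale_mm = 60, rng_seed = 1L, subdiv = 4) {
  kind <- match.arg(kind)
  stopifnot(scale_mm > 0)
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(rng_seed)
  par <- switch(kind,
    insectoid = list(nb = 16, amp = c(0.8, 1.5), sig = c(0.08, 0.15),
                     axes = c(1.3, 0.95, 1.1)),
    blob = list(nb = 10, amp = c(0.3, 1.1), sig = c(0.12, 0.30),
                axes = c(1.5, 0.9, 1.1)),
    orchidoid = list(nb = 6, amp = c(0.5, 1.2), sig = c(0.30, 0.60),
                     axes = c(1.6, 1.0, 0.7)))
  m <- icosphere(subdiv, 1)
  v <- m$vertices
  dirs <- matrix(rnorm(3 * par$nb), par$nb, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  amp <- runif(par$nb, par$amp[1], par$amp[2])
  sig <- runif(par$nb, par$sig[1], par$sig[2])
  radial <- function(u) {
    r <- rep(1, nrow(u))
    for (k in seq_len(par$nb)) {
      ang <- acos(pmin(1, pmax(-1, u %*% dirs[k, ])))
      r <- r + amp[k] * exp(-(ang / sig[k])^2)
    }
    drop(r)
  }
  v2 <- sweep(v * radial(v), 2, par$axes, `*`)
  diag0 <- sqrt(sum((apply(v2, 2, max) - apply(v2, 2, min))^2))
  s <- scale_mm / diag0
  v2 <- v2 * s
  ctr <- colMeans(v2)
  mesh <- triangle_mesh(sweep(v2, 2, ctr), m$faces)
  inside <- function(p) {
    p <- rbind(p)
    q <- sweep(sweep(p, 2, ctr, `+`) / s, 2, par$axes, `/`)
    len <- sqrt(rowSums(q^2))
    u <- q / pmax(len, 1e-12)
    len <= radial(u)
  }
  attr(mesh, "inside") <- inside
  mesh
}

#' Default photograph intrinsics of the synthetic evaluation
#'
#' A 23.6 mm APS-C sensor behind a telephoto macro framing (105 mm) so
#' that a specimen-scale object at roughly half a meter fills most of
#' the reduced 462 x 306 frame, as in close-up specimen photography.
#'
#' @param width,height reduced image size [px].
#' @param focal_mm lens focal length [mm].
#' @return a [camera_intrinsics()].
#' @export
eval_intrinsics <- function(width = 462, height = 306, focal_mm = 105) {
  camera_intrinsics(width, height, focal_mm = focal_mm,
                    sensor_width_mm = 23.6)
}

#' Synthetic camera-recovery test cases
#'
#' Samples ground-truth camera poses uniformly from the evaluation
#' ranges (`r` in [540, 560] mm, `theta` in [0, 2*pi], `phi` in
#' [-0.7*pi/2, 0.7*pi/2], `delta_x` in [0, 2*pi], `delta_y` and
#' `delta_z` in [-0.006*pi, 0.006*pi]) and renders a binary silhouette
#' "photograph" plus a flat-colored RGB photograph from each.
#'
#' @param mesh the fixture [triangle_mesh()].
#' @param n number of cases.
#' @param intr [camera_intrinsics()]; default [eval_intrinsics()].
#' @param rng_seed seed for pose sampling and the face-color table.
#' @param n_color_regions number of flat-colored surface regions of the
#'   color photographs (large contiguous regions keep region interiors
#'   exactly reconstructable; region boundaries are a vanishing
#'   fraction of the surface).
#' @return list of `eval_case` objects: `true_pose`, `silhouette`,
#'   `color_photo`, `intr`.
#' @export
make_eval_set <- function(mesh, n, intr = eval_intrinsics(),
                          rng_seed = 1L, n_color_regions = 20) {
  stopifnot(n >= 1)
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(rng_seed)
  # piecewise-constant coloring over spherical-Voronoi face regions
  seeds <- matrix(rnorm(3 * n_color_regions), n_color_regions, 3)
  seeds <- seeds / sqrt(rowSums(seeds^2))
  fc <- (mesh$vertices[mesh$faces[, 1], ] +
           mesh$vertices[mesh$faces[, 2], ] +
           mesh$vertices[mesh$faces[, 3], ]) / 3
  fdir <- fc / sqrt(rowSums(fc^2))
  region <- max.col(fdir %*% t(seeds))
  region_colors <- matrix(runif(n_color_regions * 3, 0.1, 0.9), ncol = 3)
  face_colors <- region_colors[region, , drop = FALSE]
  lapply(seq_len(n), function(i) {
    pose <- camera_pose(theta = runif(1, 0, 2 * pi),
                        phi = runif(1, -0.7 * pi / 2, 0.7 * pi / 2),
                        r = runif(1, 540, 560),
                        delta_x = runif(1, 0, 2 * pi),
                        delta_y = runif(1, -0.006 * pi, 0.006 * pi),
                        delta_z = runif(1, -0.006 * pi, 0.006 * pi))
    views <- render_views(mesh, pose, intr)
    structure(list(true_pose = pose, silhouette = views$silhouette,
                   color_photo = render_flat_color(mesh, pose, intr,
                                                   face_colors),
                   face_colors = face_colors, intr = intr),
              class = "eval_case")
  })
}

#' Synthetic CT volume of a fixture mesh
#'
#' Solid voxelization of the mesh (parity counting along voxel columns):
#' interior voxels get high intensity, exterior low, plus salt-and-
#' pepper noise on a fraction of interior-region voxels. A clean
#' all-background border shell is kept so segmentation always closes.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param voxel_mm isotropic voxel size [mm].
#' @param noise_frac fraction of voxels hit by salt/pepper noise.
#' @param rng_seed noise seed.
#' @param pad background padding [voxels] around the mesh bounding box.
#' @param fg,bg foreground/background intensities.
#' @return a [scalar_volume()].
#' @export
make_volume <- function(mesh, voxel_mm = 1, noise_frac = 0.01,
                        rng_seed = 1L, pad = 4, fg = 200, bg = 20) {
  stopifnot(voxel_mm > 0)
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(rng_seed)
  lo <- apply(mesh$vertices, 2, min) - pad * voxel_mm
  hi <- apply(mesh$vertices, 2, max) + pad * voxel_mm
  dims <- as.integer(ceiling((hi - lo) / voxel_mm))
  inside <- voxelize_cpp(mesh$vertices, mesh$faces, dims,
                         rep(voxel_mm, 3), lo)
  grid <- array(ifelse(inside, fg, bg), dims)
  if (noise_frac > 0) {
    interior <- array(FALSE, dims)
    interior[2:(dims[1] - 1), 2:(dims[2] - 1), 2:(dims[3] - 1)] <- TRUE
    hit <- which(interior & runif(length(grid)) < noise_frac)
    salt <- runif(length(hit)) < 0.5
    grid[hit[salt]] <- fg + 20
    grid[hit[!salt]] <- bg - 15
  }
  scalar_volume(grid, spacing = rep(voxel_mm, 3), origin = lo)
}

#' Error report for a batch of pose estimates
#'
#' Per-case 3D position error (Euclidean distance between true and
#' estimated camera positions), absolute wrapped rotation-angle errors,
#' and the final matching cost, with mean/median/max summaries.
#'
#' @param cases list of `eval_case` objects.
#' @param estimates list of `pose_estimate` objects, same length.
#' @return an `eval_report`: list with `per_case` (data.frame) and
#'   `summary` (matrix of mean/median/max per metric).
#' @export
evaluate_errors <- function(cases, estimates) {
  if (length(cases) != length(estimates))
    stop("cases and estimates differ in length")
  wrap <- function(a) abs(((a + pi) %% (2 * pi)) - pi)
  per <- do.call(rbind, lapply(seq_along(cases), function(i) {
    tp <- cases[[i]]$true_pose
    ep <- estimates[[i]]$pose
    data.frame(
      position_error = sqrt(sum((camera_frame(tp)$pos -
                                   camera_frame(ep)$pos)^2)),
      d_delta_x = wrap(ep$delta_x - tp$delta_x),
      d_delta_y = wrap(ep$delta_y - tp$delta_y),
      d_delta_z = wrap(ep$delta_z - tp$delta_z),
      cost = estimates[[i]]$cost,
      accepted = estimates[[i]]$accepted)
  }))
  met <- per[, c("position_error", "d_delta_x", "d_delta_y", "d_delta_z",
                 "cost")]
  structure(list(
    per_case = per,
    summary = rbind(mean = colMeans(met),
                    median = apply(met, 2, median),
                    max = apply(met, 2, max))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", nrow(x$per_case), "cases\n")
  print(round(x$summary, 4))
  invisible(x)
}
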