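#' Fill uncovered texels by boundary diffusion and smoothing
#'
#' Texels inside chart interiors that no photograph covered are filled by
#' iteratively dilating the covered set: each uncovered texel adjacent to
#' covered texels takes the mean color of its covered 4-neighbors, wave
#' by wave, until the chart interiors are complete. A few rounds of
#' 4-neighbor box smoothing are then applied to the newly filled texels
#' only, giving the blurred base that patch synthesis refines.
#'
#' @param atlas a `texture_atlas`.
#' @param layout the `atlas_layout` defining chart interiors.
#' @param smooth_iters smoothing rounds applied to filled texels.
#' @return the atlas with `covered` complete over chart interiors and a
#'   logical `filled` matrix marking the texels that were synthesized by
#'   diffusion (the originally-missing region).
#' @export
fill_and_smooth <- function(atlas, layout, smooth_iters = 10) {
  if (!any(atlas$covered)) stop("atlas has no covered texels")
  domain <- layout$face > 0
  cov <- atlas$covered
  color <- atlas$color
  filled <- matrix(FALSE, nrow(cov), ncol(cov))
  repeat {
    todo <- domain & !cov
    if (!any(todo)) break
    num <- matrix(0, nrow(cov), ncol(cov))
    den <- matrix(0, nrow(cov), ncol(cov))
    csum <- list(matrix(0, nrow(cov), ncol(cov)),
                 matrix(0, nrow(cov), ncol(cov)),
                 matrix(0, nrow(cov), ncol(cov)))
    for (off in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      cs <- shift_mat(cov, off[1], off[2])
      den <- den + cs
      for (d in 1:3)
        csum[[d]] <- csum[[d]] + shift_mat(color[, , d] * cov, off[1], off[2])
    }
    wave <- todo & den > 0
    if (!any(wave)) {
      # charts no photograph reached at all: no boundary to copy from,
      # so seed them with the mean covered color and let synthesis
      # (or smoothing) take over
      mc <- vapply(1:3, function(d) mean(color[, , d][cov]), 0)
      for (d in 1:3) {
        ch <- color[, , d]
        ch[todo] <- mc[d]
        color[, , d] <- ch
      }
      cov <- cov | todo
      filled <- filled | todo
      break
    }
    for (d in 1:3) {
      ch <- color[, , d]
      ch[wave] <- csum[[d]][wave] / den[wave]
      color[, , d] <- ch
    }
    cov <- cov | wave
    filled <- filled | wave
  }
  if (smooth_iters > 0 && any(filled)) {
    for (it in seq_len(smooth_iters)) {
      num <- list(matrix(0, nrow(cov), ncol(cov)),
                  matrix(0, nrow(cov), ncol(cov)),
                  matrix(0, nrow(cov), ncol(cov)))
      den <- matrix(0, nrow(cov), ncol(cov))
      for (off in list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        cs <- shift_mat(cov, off[1], off[2])
        den <- den + cs
        for (d in 1:3)
          num[[d]] <- num[[d]] + shift_mat(color[, , d] * cov, off[1], off[2])
      }
      for (d in 1:3) {
        ch <- color[, , d]
        ch[filled] <- num[[d]][filled] / pmax(den[filled], 1)
        color[, , d] <- ch
      }
    }
  }
  atlas$color <- color
  atlas$covered <- cov
  atlas$filled <- filled
  atlas$source_id[filled] <- -1L  # synthetic texels are flagged
  atlas
}

# shift a matrix by (dr, dc), padding with zeros/FALSE
shift_mat <- function(m, dr, dc) {
  out <- matrix(if (is.logical(m[1])) FALSE else 0, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Exemplar-based patch synthesis over the filled region
#'
#' Refines the blurred diffusion fill with texture synthesized from the
#' photographed surface. Reference patches are sampled at
#' surface-area-uniform random points and their k x k color grids are
#' read from the chart's planar parameterization (charts are near-flat,
#' so the local chart plane approximates the geodesic patch frame);
#' patches touching the originally-missing region are discarded. Target
#' patches are built the same way at random texels of the missing
#' region; each target is matched to its L2-nearest reference and the
#' reference is alpha-blended (cosine falloff) around the target. The
#' search-blend round is repeated `n_iters` times. Only
#' originally-missing texels are modified; synthesized texels are
#' flagged with source id -1.
#'
#' @param atlas a `texture_atlas` after [fill_and_smooth()].
#' @param mesh the [triangle_mesh()].
#' @param layout the `atlas_layout`.
#' @param n_ref number of reference patches.
#' @param patch_k samples per patch side.
#' @param radius_texels patch half-width in texels.
#' @param n_iters search-and-blend rounds.
#' @param n_targets_per_iter target points sampled per round.
#' @param rng_seed seed controlling patch placement (bit-reproducible).
#' @return the atlas with the missing region resynthesized.
#' @export
synthesize_patches <- function(atlas, mesh, layout, n_ref = 2000,
                               patch_k = 9, radius_texels = 5,
                               n_iters = 3, n_targets_per_iter = 400,
                               rng_seed = 1L) {
  if (is.null(atlas$filled))
    stop("run fill_and_smooth before synthesize_patches")
  missing0 <- atlas$filled
  if (!any(missing0)) return(atlas)
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(rng_seed)
  res <- layout$resolution
  offs <- seq(-radius_texels, radius_texels, length.out = patch_k)
  og <- expand.grid(dr = offs, dc = offs)
  alpha <- matrix(cos(pi / 2 * sqrt(og$dr^2 + og$dc^2) /
                        (radius_texels * sqrt(2))),
                  patch_k * patch_k, 1)
  alpha <- pmax(alpha, 0)

  # sample patch grids; valid iff all samples stay in the same chart and
  # (for references) outside the originally-missing region
  grab <- function(centers, forbid_missing) {
    npt <- nrow(centers)
    vals <- matrix(NA_real_, npt, patch_k * patch_k * 3)
    valid <- rep(TRUE, npt)
    cid0 <- layout$chart_id[centers]
    for (s in seq_len(nrow(og))) {
      r <- centers[, 1] + og$dr[s]
      c_ <- centers[, 2] + og$dc[s]
      ri <- round(r); ci <- round(c_)
      ok <- ri >= 1 & ri <= res & ci >= 1 & ci <= res
      lin <- (pmax(pmin(ci, res), 1) - 1L) * res + pmax(pmin(ri, res), 1)
      ok <- ok & layout$chart_id[lin] == cid0
      if (forbid_missing) ok <- ok & !missing0[lin]
      valid <- valid & ok
      for (d in 1:3)
        vals[, (s - 1) * 3 + d] <- atlas$color[, , d][lin]
    }
    list(vals = vals, valid = valid)
  }

  # surface-area-uniform reference points mapped through the chart uvs
  areas <- face_areas(mesh)
  fsel <- sample.int(nrow(mesh$faces), n_ref, replace = TRUE, prob = areas)
  b1 <- runif(n_ref); b2 <- runif(n_ref)
  flip <- b1 + b2 > 1
  b1[flip] <- 1 - b1[flip]; b2[flip] <- 1 - b2[flip]
  fu <- layout$face_uv
  row_of <- match(fsel, fu$fid)
  uvc <- fu$uv[fu$tri[row_of, 1], , drop = FALSE] * (1 - b1 - b2) +
    fu$uv[fu$tri[row_of, 2], , drop = FALSE] * b1 +
    fu$uv[fu$tri[row_of, 3], , drop = FALSE] * b2
  ref_centers <- cbind(pmin(pmax(round((1 - uvc[, 2]) * res + 0.5), 1), res),
                       pmin(pmax(round(uvc[, 1] * res + 0.5), 1), res))
  refs <- grab(ref_centers, forbid_missing = TRUE)
  R <- refs$vals[refs$valid, , drop = FALSE]
  if (nrow(R) == 0)
    stop("no valid reference patches: missing region too large")

  miss_idx <- which(missing0)
  color <- atlas$color
  for (iter in seq_len(n_iters)) {
    tgt <- sample(miss_idx, min(n_targets_per_iter, length(miss_idx)))
    centers <- cbind(((tgt - 1L) %% res) + 1L, ((tgt - 1L) %/% res) + 1L)
    atlas$color <- color
    tp <- grab(centers, forbid_missing = FALSE)
    use <- which(tp$valid)
    if (!length(use)) next
    # nearest reference by squared L2
    d2 <- outer(rowSums(tp$vals[use, , drop = FALSE]^2),
                rowSums(R^2), `+`) -
      2 * tp$vals[use, , drop = FALSE] %*% t(R)
    bestr <- max.col(-d2, ties.method = "first")
    for (ti in seq_along(use)) {
      ctr <- centers[use[ti], ]
      pv <- R[bestr[ti], ]
      for (s in seq_len(nrow(og))) {
        ri <- round(ctr[1] + og$dr[s]); ci <- round(ctr[2] + og$dc[s])
        if (ri < 1 || ri > res || ci < 1 || ci > res) next
        if (!missing0[ri, ci]) next
        a <- alpha[s]
        for (d in 1:3)
          color[ri, ci, d] <- (1 - a) * color[ri, ci, d] +
            a * pv[(s - 1) * 3 + d]
      }
    }
  }
  atlas$color <- color
  atlas$source_id[missing0] <- -1L
  atlas
}
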