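# shift a 3D array along one axis, zero filled
abind_shift <- function(a, by, axis) {
  out <- array(if (is.logical(a)) FALSE else 0, dim(a))
  n <- dim(a)[axis]
  src <- max(1, 1 - by):min(n, n - by)
  dst <- src + by
  idx_src <- list(1:dim(a)[1], 1:dim(a)[2], 1:dim(a)[3])
  idx_dst <- idx_src
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

test_that("segmentation recovers an analytic sphere despite salt noise", {
  d <- c(40, 40, 40)
  ctr <- c(20, 20, 20)
  ii <- array(rep(1:40, times = 40 * 40), d)
  jj <- array(rep(rep(1:40, each = 40), times = 40), d)
  kk <- array(rep(1:40, each = 40 * 40), d)
  sphere <- (ii - 0.5 - ctr[1])^2 + (jj - 0.5 - ctr[2])^2 +
    (kk - 0.5 - ctr[3])^2 <= 13^2
  g <- array(20, d)
  g[sphere] <- 200
  set.seed(8)
  salt <- !sphere & array(runif(prod(d)) < 0.01, d)
  # keep salt isolated: no voxel 6-adjacent to the sphere
  near <- sphere
  for (off in 1:2) {
    near <- near | abind_shift(sphere, off, 1) | abind_shift(sphere, -off, 1) |
      abind_shift(sphere, off, 2) | abind_shift(sphere, -off, 2) |
      abind_shift(sphere, off, 3) | abind_shift(sphere, -off, 3)
  }
  salt <- salt & !near
  g[salt] <- 200
  vol <- scalar_volume(g)
  lab <- segment_foreground(vol, threshold = 100, opening_radius = 1,
                            closing_radius = 0)
  lab <- array(lab, d)
  # every salt voxel is gone, nothing appears outside the sphere, and at
  # most a one-voxel boundary shell of the discrete sphere is eroded
  expect_false(any(lab[salt]))
  expect_false(any(lab & !sphere))
  core <- (ii - 0.5 - ctr[1])^2 + (jj - 0.5 - ctr[2])^2 +
    (kk - 0.5 - ctr[3])^2 <= 12^2
  expect_true(all(lab[core]))
  expect_error(segment_foreground(scalar_volume(array(5, c(4, 4, 4))), 100),
               "empty segmentation")
})

test_that("hollow cavities are filled solid", {
  d <- c(24, 24, 24)
  ii <- array(rep(1:24, times = 24 * 24), d)
  jj <- array(rep(rep(1:24, each = 24), times = 24), d)
  kk <- array(rep(1:24, each = 24 * 24), d)
  r2 <- (ii - 12.5)^2 + (jj - 12.5)^2 + (kk - 12.5)^2
  shell <- r2 <= 9^2 & r2 >= 6^2
  g <- array(10, d)
  g[shell] <- 200
  lab <- segment_foreground(scalar_volume(g), 100, opening_radius = 0,
                            closing_radius = 0)
  expect_true(all(lab[r2 <= 5.5^2]))   # cavity now foreground
  expect_false(any(lab[r2 > 9.5^2]))   # outside untouched
})

test_that("segmentation is idempotent on its own output", {
  mesh <- make_mesh("orchidoid", 40, rng_seed = 5, subdiv = 3)
  vol <- make_volume(mesh, voxel_mm = 1.2, noise_frac = 0, rng_seed = 2)
  lab <- segment_foreground(vol, 100, opening_radius = 0, closing_radius = 0)
  again <- segment_foreground(scalar_volume(lab * 1), 0.5,
                              opening_radius = 0, closing_radius = 0)
  expect_identical(array(again, dim(lab)), array(lab, dim(lab)))
})

test_that("isosurface of a digitized sphere has the right area and closes", {
  d <- c(48, 48, 48)
  ii <- array(rep(1:48, times = 48 * 48), d)
  jj <- array(rep(rep(1:48, each = 48), times = 48), d)
  kk <- array(rep(1:48, each = 48 * 48), d)
  sphere <- (ii - 24.5)^2 + (jj - 24.5)^2 + (kk - 24.5)^2 <= 20^2
  m <- extract_surface(sphere)
  expect_true(phototex:::mesh_is_watertight(m))
  expect_lt(abs(phototex:::mesh_surface_area(m) / (4 * pi * 20^2) - 1), 0.05)
  # vertices near radius 20 from the center
  rad <- sqrt(rowSums(sweep(m$vertices, 2, c(24.5, 24.5, 24.5))^2))
  expect_lt(max(abs(rad - 20)), 1.8)
  expect_error(extract_surface(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("isosurface agrees with an independent marching-cubes program", {
  d <- c(32, 32, 32)
  ii <- array(rep(1:32, times = 32 * 32), d)
  jj <- array(rep(rep(1:32, each = 32), times = 32), d)
  kk <- array(rep(1:32, each = 32 * 32), d)
  blob <- (ii - 16.5)^2 / 1.44 + (jj - 16.5)^2 + (kk - 16.5)^2 / 0.81 <= 11^2
  m <- extract_surface(blob, smooth_iters = 1)
  script <- tempfile(fileext = ".py")
  outcsv <- tempfile(fileext = ".csv")
  writeLines(c(
    "import numpy as np",
    "from skimage import measure",
    "d = (32, 32, 32)",
    "i, j, k = np.meshgrid(np.arange(1, 33), np.arange(1, 33), np.arange(1, 33), indexing='ij')",
    "blob = ((i - 16.5)**2 / 1.44 + (j - 16.5)**2 + (k - 16.5)**2 / 0.81 <= 11**2).astype(float)",
    "sm = blob.copy()",
    "from scipy.ndimage import uniform_filter",
    "sm = uniform_filter(blob, size=3, mode='constant')",
    "v, f, _, _ = measure.marching_cubes(np.pad(sm, 1), 0.5)",
    sprintf("np.savetxt(%s, v - 0.5, delimiter=',')", deparse(outcsv))),
    script)
  status <- system2("python", script, stdout = NULL, stderr = NULL)
  expect_identical(status, 0L)
  ref <- as.matrix(read.csv(outcsv, header = FALSE))
  # same surface up to sub-voxel discretization differences: compare
  # sampled nearest-point distances both ways
  set.seed(4)
  a <- m$vertices[sample(nrow(m$vertices), 200), ]
  b <- ref[sample(nrow(ref), 200), ]
  d_ab <- max(apply(a, 1, function(p)
    sqrt(min(rowSums(sweep(ref, 2, p)^2)))))
  d_ba <- max(apply(b, 1, function(p)
    sqrt(min(rowSums(sweep(m$vertices, 2, p)^2)))))
  expect_lt(max(d_ab, d_ba), 1.0)
  unlink(c(script, outcsv))
})

test_that("solid voxelization matches a ray-parity point-in-mesh oracle", {
  mesh <- make_mesh("orchidoid", 36, rng_seed = 9, subdiv = 2)
  vol <- make_volume(mesh, voxel_mm = 1.5, noise_frac = 0, rng_seed = 1)
  d <- dim(vol$grid)
  set.seed(14)
  ijk <- cbind(sample(d[1], 300, TRUE), sample(d[2], 300, TRUE),
               sample(d[3], 300, TRUE))
  pts <- sweep(sweep(ijk - 0.5, 2, vol$spacing, `*`), 2, vol$origin, `+`)
  vox_in <- vol$grid[ijk] > 100
  ora <- inside_mesh_oracle(pts, mesh)
  expect_gt(mean(vox_in == ora), 0.995)
})

test_that("volume -> labels -> surface round trip stays within 2 voxel diagonals", {
  mesh <- make_mesh("orchidoid", 45, rng_seed = 3, subdiv = 3)
  vol <- make_volume(mesh, voxel_mm = 1, noise_frac = 0.01, rng_seed = 4)
  lab <- segment_foreground(vol, 100, opening_radius = 0, closing_radius = 0)
  m2 <- extract_surface(lab, vol$spacing, vol$origin)
  expect_true(phototex:::mesh_is_edge_manifold(m2))
  set.seed(6)
  samp <- function(A, B, n = 500) {
    max(apply(A[sample(nrow(A), min(n, nrow(A))), ], 1, function(p)
      sqrt(min(rowSums(sweep(B, 2, p)^2)))))
  }
  h <- max(samp(m2$vertices, mesh$vertices), samp(mesh$vertices, m2$vertices))
  expect_lte(h, 2 * sqrt(3))
})

test_that("volumes round-trip through TIFF and raw formats", {
  g <- array(sample(0:255, 4 * 5 * 6, TRUE), c(4, 5, 6))
  vol <- scalar_volume(g, spacing = c(0.5, 0.5, 0.8))
  tif <- tempfile(fileext = ".tif")
  write_volume(vol, tif)
  back <- read_volume(tif)
  expect_equal(back$grid * max(g), g, tolerance = 1)
  expect_equal(back$spacing, vol$spacing)
  raw <- tempfile(fileext = ".raw")
  write_volume(vol, raw, dtype = "uint16")
  back2 <- read_volume(raw)
  expect_identical(array(as.numeric(back2$grid), dim(g)),
                   array(as.numeric(g), dim(g)))
  unlink(c(tif, paste0(tif, ".json"), raw, paste0(raw, ".json")))
})
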