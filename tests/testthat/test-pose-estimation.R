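# shared small setup: coarse solver on a subdivision-3 fixture
pose_to_vector_test <- function(p) c(p$theta, p$phi, p$r, p$delta_x,
                                     p$delta_y, p$delta_z)
pe_mesh <- small_mesh()
pe_intr <- eval_intrinsics(232, 154, focal_mm = 52.5)  # half-size frame
pe_cfg <- search_config(r0 = 550, n_sphere = 42, r_offsets = c(0, -10, 10),
                        n_hill = 120, n_starts = 2, rng_seed = 7,
                        render_width = 232, render_height = 154)
pe_cache <- pose_search_cache(pe_mesh, pe_intr, pe_cfg)

test_that("sphere directions are unit, counted, and well separated", {
  d <- sphere_directions(2562)
  expect_equal(nrow(d), 2562)
  v <- cbind(cos(d[, 2]) * cos(d[, 1]), sin(d[, 2]),
             -cos(d[, 2]) * sin(d[, 1]))
  expect_equal(rowSums(v^2), rep(1, 2562), tolerance = 1e-12)
  # pairwise separation at n = 162 vs the ideal uniform spacing
  d2 <- sphere_directions(162)
  v2 <- cbind(cos(d2[, 2]) * cos(d2[, 1]), sin(d2[, 2]),
              -cos(d2[, 2]) * sin(d2[, 1]))
  gram <- v2 %*% t(v2)
  diag(gram) <- -1
  min_sep <- acos(max(gram))
  ideal <- sqrt(4 * pi / 162)
  expect_gt(min_sep, 0.5 * ideal)
  expect_error(sphere_directions(10), "at least 12")
  expect_error(sphere_directions(100), "icosphere")
})

test_that("coarse search returns the exhaustive minimizer", {
  case <- make_eval_set(pe_mesh, 1, pe_intr, rng_seed = 31)[[1]]
  cfg0 <- pe_cfg
  cfg0$rank_boundary_cap <- 0   # exact ranking for the oracle comparison
  ini <- initial_search(case$silhouette, pe_mesh, pe_intr, cfg0, pe_cache)
  # independent loop: evaluate every candidate with the public metric
  D <- distance_field(case$silhouette)
  best <- Inf; best_i <- NA
  for (i in seq_len(nrow(pe_cache$candidates))) {
    if (is.null(pe_cache$bpts[[i]])) next
    cn <- pe_cache$candidates[i, ]
    al <- aligned_distance(case$silhouette,
                           render_silhouette(pe_mesh,
                                             camera_pose(cn[1], cn[2], cn[3]),
                                             pe_intr),
                           photo_dt = D)
    if (al$cost < best) { best <- al$cost; best_i <- i }
  }
  expect_equal(ini$aligned_cost, best, tolerance = 1e-9)
  expect_equal(unname(pose_to_vector_test(ini$pose)[1:3]),
               unname(pe_cache$candidates[best_i, ]))
})

test_that("exact grid poses are recovered with near-zero cost", {
  cn <- pe_cache$candidates[100, ]
  true_pose <- camera_pose(cn[1], cn[2], cn[3])
  photo <- render_silhouette(pe_mesh, true_pose, pe_intr)
  ini <- initial_search(photo, pe_mesh, pe_intr, pe_cfg, pe_cache)
  expect_lt(ini$aligned_cost, 0.05)
  est <- estimate_camera_pose(photo, pe_mesh, pe_intr, pe_cfg, pe_cache)
  expect_lte(est$cost, 0.05)
  expect_true(est$accepted)
})

test_that("gradient descent is monotone and fixes small perturbations", {
  true_pose <- camera_pose(1.0, 0.25, 551, 0.5, 0.004, -0.003)
  photo <- render_silhouette(pe_mesh, true_pose, pe_intr)
  D <- distance_field(photo)
  # at the optimum the cost is 0 and the pose must not move
  gd0 <- refine_gradient_descent(true_pose, photo, pe_mesh, pe_intr, pe_cfg,
                                 D)
  expect_equal(gd0$cost, 0)
  expect_equal(pose_to_vector_test(gd0$pose), pose_to_vector_test(true_pose))
  # +1 degree in theta: descent must strictly reduce the position error
  pert <- camera_pose(1.0 + pi / 180, 0.25, 551, 0.5, 0.004, -0.003)
  gd <- refine_gradient_descent(pert, photo, pe_mesh, pe_intr, pe_cfg, D)
  e0 <- sqrt(sum((camera_frame(true_pose)$pos - camera_frame(pert)$pos)^2))
  e1 <- sqrt(sum((camera_frame(true_pose)$pos - camera_frame(gd$pose)$pos)^2))
  expect_lt(e1, e0)
  expect_lte(gd$cost, phototex:::pose_cost(pose_to_vector_test(pert), D,
                                           pe_mesh, pe_intr))
})

test_that("hill climbing only accepts improvements and is seeded", {
  true_pose <- camera_pose(2.2, -0.4, 548)
  photo <- render_silhouette(pe_mesh, true_pose, pe_intr)
  D <- distance_field(photo)
  # at a perfect optimum every proposal is rejected
  hc0 <- refine_hill_climb(true_pose, photo, pe_mesh, pe_intr, pe_cfg, D)
  expect_equal(hc0$cost, 0)
  expect_equal(pose_to_vector_test(hc0$pose), pose_to_vector_test(true_pose))
  # identical seeds give bit-identical results; the caller RNG is untouched
  start <- camera_pose(2.25, -0.38, 552)
  set.seed(123); before <- runif(1)
  h1 <- refine_hill_climb(start, photo, pe_mesh, pe_intr, pe_cfg, D)
  set.seed(123)
  h2 <- refine_hill_climb(start, photo, pe_mesh, pe_intr, pe_cfg, D)
  expect_identical(pose_to_vector_test(h1$pose), pose_to_vector_test(h2$pose))
  set.seed(123)
  expect_identical(before, runif(1))
  # never worse than its input
  expect_lte(h1$cost, phototex:::pose_cost(pose_to_vector_test(start), D,
                                           pe_mesh, pe_intr))
})

test_that("the three-stage pipeline is cost-monotone and self-consistent", {
  cases <- make_eval_set(pe_mesh, 3, pe_intr, rng_seed = 44)
  for (cs in cases) {
    est <- estimate_camera_pose(cs$silhouette, pe_mesh, pe_intr, pe_cfg,
                                pe_cache)
    tr <- est$trace
    expect_gte(tr["initial"], tr["gradient_descent"])
    expect_gte(tr["gradient_descent"], tr["hill_climb"])
    # reported cost equals the metric on a re-render from the estimate
    rerender <- render_silhouette(pe_mesh, est$pose, pe_intr)
    expect_equal(silhouette_distance(cs$silhouette, rerender), est$cost,
                 tolerance = 1e-12)
    expect_identical(est$accepted, est$cost < pe_cfg$discard_threshold)
  }
})

test_that("unmatchable noise silhouettes are discarded", {
  set.seed(77)
  # sparse scattered specks: the distance field is large between them,
  # so no single connected silhouette can hug their boundaries
  noise <- matrix(runif(232 * 154) < 0.004, 154, 232)
  est <- estimate_camera_pose(noise, pe_mesh, pe_intr, pe_cfg, pe_cache)
  expect_gte(est$cost, pe_cfg$discard_threshold)
  expect_false(est$accepted)
  expect_error(estimate_camera_pose(matrix(FALSE, 154, 232), pe_mesh,
                                    pe_intr, pe_cfg, pe_cache), "empty")
})
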