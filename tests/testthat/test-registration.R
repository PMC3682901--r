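test_that("pre-initialization aligns centroids and applies the hint", {
  g_truth <- rigid_transform(10, -5, 3)     # pure shift
  pair <- registration_pair(g_truth)
  init <- preinitialize(pair$fixed, pair$moving)
  expect_lt(max(abs(c(init$tx, init$ty, init$tz) - c(10, -5, 3))), 2)
  # identical images: identity within numerical noise
  init0 <- preinitialize(pair$fixed, pair$fixed)
  expect_lt(max(abs(c(init0$tx, init0$ty, init0$tz))), 1e-6)
  expect_identical(c(init0$rx, init0$ry, init0$rz), c(0, 0, 0))
  # hinted rotation leaves only a small residual on a rotated phantom
  g_rot <- rigid_transform(0, 0, 0, 0, 0, 0, 0, 0, 40)
  pair_rot <- registration_pair(g_rot)
  init_rot <- preinitialize(pair_rot$fixed, pair_rot$moving, hint = 40)
  expect_lt(abs(rt_angles(init_rot)[["rz"]] - 40), 5)
  # all-constant image has no centroid
  flat <- image_volume(array(0, c(8, 8, 8)), c(0, 0, 0), c(1, 1, 1))
  expect_error(preinitialize(flat, flat), "centroid undefined")
})

test_that("registration recovers a known rigid motion to subvoxel accuracy", {
  g_truth <- rigid_transform(8, -4, 6, 0, 0, 0, 0, 0, 10)
  pair <- registration_pair(g_truth)
  res <- register_rigid(pair$fixed, pair$moving)
  err <- transform_errors(res$transform, g_truth)
  expect_lt(err[["translation"]], 0.5 * min(pair$spec$spacing))
  expect_lt(err[["angle"]], 0.5)
  # moving = fixed: identity within tolerance
  res_id <- register_rigid(pair$fixed, pair$fixed)
  err_id <- transform_errors(res_id$transform, rt_identity())
  expect_lt(err_id[["translation"]], 0.5)
  expect_lt(err_id[["angle"]], 0.25)
  expect_lte(res_id$metric, res$metric)   # self-match is the metric optimum
})

test_that("seeded registrations are bit-identical", {
  g_truth <- rigid_transform(6, 3, -4, 0, 0, 0, 0, 0, 25)
  pair <- registration_pair(g_truth)
  init <- preinitialize(pair$fixed, pair$moving, hint = 25)
  r1 <- register_rigid(pair$fixed, pair$moving, init)
  r2 <- register_rigid(pair$fixed, pair$moving, init)
  expect_identical(unclass(r1$transform), unclass(r2$transform))
  expect_identical(r1$metric, r2$metric)
})

test_that("apply_transform matches lattice shifts and inverts cleanly", {
  pair <- registration_pair(rigid_transform())
  vol <- pair$fixed
  # identity, nearest: voxelwise equal
  same <- apply_transform(vol, rt_identity(), vol, "nearest")
  expect_equal(same$voxels, vol$voxels)
  expect_identical(same$outside_count, 0L)
  # shift by exactly one voxel spacing, nearest: array index shift
  t1 <- rigid_transform(tx = vol$spacing[1])
  shifted <- apply_transform(vol, t1, vol, "nearest", fill = -1000)
  d <- dim(vol$voxels)
  expect_equal(shifted$voxels[1:(d[1] - 1), , ], vol$voxels[2:d[1], , ])
  # T then T^-1 (linear) on a smooth volume: small mean interior error
  g <- centered_grid(c(48L, 48L, 32L), c(2.5, 2.5, 3))
  p <- voxel_centers(g)
  smooth <- image_volume(
    array(800 * exp(-rowSums(p^2) / (2 * 30^2)) +
            300 * exp(-rowSums(sweep(p, 2, c(25, -15, 10))^2) / (2 * 18^2)),
          grid_dim(g)), g$origin, g$spacing)
  t <- rigid_transform(3.3, -2.1, 1.7, 0, 0, 0, 0, 0, 8)
  fwd <- apply_transform(smooth, t, smooth, "linear", fill = NA_real_)
  back <- apply_transform(fwd, rt_invert(t), smooth, "linear",
                          fill = NA_real_)
  interior <- !is.na(back$voxels) & !is.na(smooth$voxels)
  core <- abs(back$voxels - smooth$voxels)[interior]
  expect_lt(mean(core), 0.01 * diff(range(smooth$voxels)))
})

test_that("transform_roi maps vertices point-wise and preserves volume", {
  planes <- seq(-28.5, 28.5, 3)
  s <- sphere_roi("s", c(4, -2, 0), 18, planes, n_vertices = 128)
  expect_identical(transform_roi(s, rt_identity())$contours, s$contours)
  up5 <- transform_roi(s, rigid_transform(tz = 5))
  expect_equal(vapply(up5$contours, function(ct) ct[1, 3], numeric(1)),
               vapply(s$contours, function(ct) ct[1, 3], numeric(1)) + 5)
  # axial rotation about the centroid: voxelized volume changes < 2%
  rot <- transform_roi(s, rigid_transform(rpx = 4, rpy = -2, rz = 30))
  g <- centered_grid(c(48L, 48L, 20L), c(1.5, 1.5, 3))
  v0 <- mask_volume_ml(voxelize(s, g))
  v1 <- mask_volume_ml(voxelize(rot, g))
  expect_lt(abs(v1 - v0) / v0, 0.02)
  # a genuinely tilted contour is flattened with a warning
  tilt <- rigid_transform(rx = 20)
  expect_warning(transform_roi(s, tilt), "out of plane")
})
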