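test_that("uniform dose gives degenerate statistics and a step DVH", {
  g <- centered_grid(c(20L, 20L, 10L), c(2, 2, 3))
  dose <- image_volume(array(44.5, c(20, 20, 10)), g$origin, g$spacing)
  b <- box_roi("b", c(-12, -12, -9), c(12, 12, 9), grid_planes(g))
  s <- sample_dose(dose, voxelize(b, dose))
  expect_true(all(abs(s$dose_gy - 44.5) < 1e-9))
  st <- dose_stats(s, 0.8 * 44.5)
  expect_equal(st$min_gy, 44.5)
  expect_equal(st$max_gy, 44.5)
  expect_equal(st$median_gy, 44.5)
  expect_equal(st$vol_in_isodose_ml, st$recurrence_vol_ml)
  dvh <- compute_dvh(s, 0.5)
  expect_true(all(diff(dvh$volume_ml) <= 1e-12))          # non-increasing
  expect_equal(dvh$volume_ml[1], st$recurrence_vol_ml)     # DVH(0) = total
  # step: full volume at-or-below the uniform dose, zero above
  expect_equal(dvh$volume_ml[dvh$dose_edges <= 44.5],
               rep(st$recurrence_vol_ml, sum(dvh$dose_edges <= 44.5)))
  expect_equal(dvh$volume_ml[dvh$dose_edges > 44.5],
               rep(0, sum(dvh$dose_edges > 44.5)))
})

test_that("a linear gradient over a centered box yields the analytic statistics", {
  dose <- gradient_dose(c(24L, 24L, 50L), c(4, 4, 2), 0, 50)
  planes <- grid_planes(dose)
  b <- box_roi("b", c(-30, -30, min(planes) - 1), c(30, 30, max(planes) + 1),
               planes)
  s <- sample_dose(dose, voxelize(b, dose))
  st <- dose_stats(s, 0.8 * 50)
  expect_equal(st$median_gy, 25, tolerance = 0.004)        # midpoint
  expect_equal(weighted.mean(s$dose_gy, s$volume_ml), 25,
               tolerance = 0.004)                          # symmetry
  expect_equal(st$vol_in_isodose_ml / st$recurrence_vol_ml, 0.2,
               tolerance = 0.01)                           # top 20%
  # cumulative DVH of a uniform dose density is linear in dose
  dvh <- compute_dvh(s, 0.1)
  mid <- dvh$dose_edges > 2 & dvh$dose_edges < 48
  fit <- stats::lm(dvh$volume_ml[mid] ~ dvh$dose_edges[mid])
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("two equal-volume dose levels give two equal differential bins", {
  s <- data.frame(dose_gy = c(10, 40), volume_ml = c(5, 5), defined = TRUE)
  d <- compute_dvh(s, 1, "differential")
  nz <- which(d$volume_ml > 0)
  expect_length(nz, 2)
  expect_equal(unname(d$volume_ml[nz]), c(5, 5))
  expect_equal(sum(d$volume_ml), d$total_volume_ml)
})

test_that("DVH of disjoint masks adds bin-wise", {
  dose <- gradient_dose(c(16L, 16L, 20L), c(4, 4, 3), 0, 45)
  planes <- grid_planes(dose)
  b1 <- box_roi("a", c(-25, -25, planes[2]), c(0, 0, planes[8]), planes)
  b2 <- box_roi("b", c(5, 5, planes[10]), c(25, 25, planes[18]), planes)
  m1 <- voxelize(b1, dose); m2 <- voxelize(b2, dose)
  u <- voxel_mask(pmax(m1$occupancy, m2$occupancy), m1$origin, m1$spacing)
  bw <- 0.25
  du <- compute_dvh(sample_dose(dose, u), bw)
  d1 <- compute_dvh(sample_dose(dose, m1), bw)
  d2 <- compute_dvh(sample_dose(dose, m2), bw)
  pad <- function(d, n) c(d$volume_ml, rep(0, n - length(d$volume_ml)))
  n <- max(length(du$volume_ml), length(d1$volume_ml), length(d2$volume_ml))
  expect_equal(pad(du, n), pad(d1, n) + pad(d2, n), tolerance = 1e-9)
})

test_that("statistics match a 10x supersampled brute-force enumeration", {
  grid <- centered_grid(c(16L, 16L, 12L), c(3, 3, 3))
  center <- c(1.5, -3, 0); radius <- 14
  dose_fn <- function(p) 10 + p[, 3] * 1.2 + p[, 1] * 0.4  # affine field
  dose <- image_volume(array(dose_fn(voxel_centers(grid)), grid_dim(grid)),
                       grid$origin, grid$spacing)
  inside_fn <- function(p) (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 +
    (p[, 3] - center[3])^2 <= radius^2
  threshold <- 12
  oracle <- brute_force_stats(grid, inside_fn, dose_fn, threshold, ss = 10L)
  s <- sample_dose(dose, voxelize(sphere_roi("s", center, radius,
                                             grid_planes(grid),
                                             n_vertices = 256), dose))
  st <- dose_stats(s, threshold)
  dose_scale <- diff(range(dose$voxels))
  expect_equal(st$recurrence_vol_ml, oracle$volume_ml, tolerance = 0.01)
  expect_equal(st$median_gy, oracle$median, tolerance = 0.01)
  expect_equal(st$vol_in_isodose_ml, oracle$vol_in_isodose_ml,
               tolerance = 0.015)
  # extremes sit on the discretized surface: compare on the dose-range scale
  expect_lt(abs(st$min_gy - oracle$min), 0.01 * dose_scale)
  expect_lt(abs(st$max_gy - oracle$max), 0.01 * dose_scale)
})

test_that("out-of-grid voxels are tagged dose-undefined, never zeroed", {
  dose <- image_volume(array(30, c(10, 10, 10)), c(0, 0, 0), c(3, 3, 3))
  # mask grid extends beyond the dose grid in +z by half its height:
  # slices at z = 0..27 land on the dose grid, z = 30..57 fall outside
  g <- grid_geometry(c(10L, 10L, 20L), c(0, 0, 0), c(3, 3, 3))
  b <- box_roi("b", c(3, 3, -1), c(24, 24, 58), grid_planes(g))
  m <- voxelize(b, g)
  s <- sample_dose(dose, m)
  undef_frac <- sum(s$volume_ml[!s$defined]) / sum(s$volume_ml)
  expect_equal(undef_frac, 0.5, tolerance = 0.02)
  st <- dose_stats(s, 25)
  expect_equal(st$min_gy, 30)   # undefined samples never enter the minimum
  expect_equal(st$undefined_vol_ml, sum(s$volume_ml[!s$defined]))
  # beyond 50% undefined is a grid mismatch -> error
  g2 <- grid_geometry(c(10L, 10L, 30L), c(0, 0, 0), c(3, 3, 3))
  b2 <- box_roi("b", c(3, 3, -1), c(24, 24, 88), grid_planes(g2))
  expect_error(sample_dose(dose, voxelize(b2, g2)), "grid mismatch")
})

test_that("dose statistics are invariant under simultaneous rigid motion", {
  # rotate both the structure and the dose field by the same axial motion:
  # the statistics must not change beyond interpolation tolerance
  grid <- centered_grid(c(30L, 30L, 16L), c(3, 3, 3))
  center <- c(6, 3, 0); radius <- 16
  dose_fn <- function(p) 20 + 0.8 * p[, 1] + 0.5 * p[, 2]
  t <- rigid_transform(tx = 4, ty = -5, rz = 25)
  s0 <- sphere_roi("s", center, radius, grid_planes(grid), n_vertices = 256)
  dose0 <- image_volume(array(dose_fn(voxel_centers(grid)), grid_dim(grid)),
                        grid$origin, grid$spacing)
  st0 <- dose_stats(sample_dose(dose0, voxelize(s0, dose0)), 30)
  # moved scene: structure vertices through t, dose field composed with t^-1
  s1 <- transform_roi(s0, t)
  inv <- rt_invert(t)
  dose1 <- image_volume(
    array(dose_fn(rt_apply(inv, voxel_centers(grid))), grid_dim(grid)),
    grid$origin, grid$spacing)
  st1 <- dose_stats(sample_dose(dose1, voxelize(s1, dose1)), 30)
  dose_range <- diff(range(dose0$voxels))
  expect_lt(abs(st1$median_gy - st0$median_gy), 0.005 * dose_range)
  expect_lt(abs(st1$recurrence_vol_ml - st0$recurrence_vol_ml) /
              st0$recurrence_vol_ml, 0.01)
  expect_lt(abs(st1$vol_in_isodose_ml - st0$vol_in_isodose_ml) /
              st0$recurrence_vol_ml, 0.01)
})
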