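test_that("isodose masks follow the threshold geometry", {
  uni <- image_volume(array(44.5, c(10, 10, 6)), c(0, 0, 0), c(4, 4, 4))
  expect_warning(m <- isodose_mask(uni, 80, 44.5), "whole grid")
  expect_true(all(m$occupancy == 1))
  grad <- gradient_dose(c(12L, 12L, 50L), c(4, 4, 2), 0, 50)
  m80 <- isodose_mask(grad, 80, 50)
  frac <- sum(m80$occupancy) / length(m80$occupancy)
  expect_equal(frac, 0.2, tolerance = 1 / 50)      # top 20% of the gradient
  expect_warning(m0 <- isodose_mask(grad, 100, 60), "empty")
  expect_equal(sum(m0$occupancy), 0)
})

test_that("overlap is exact on constructed fixtures and symmetric in ml", {
  g <- grid_geometry(c(40L, 40L, 10L), c(0, 0, 0), c(1, 1, 2))
  zp <- grid_planes(g)
  a <- voxelize(box_roi("a", c(4.5, 4.5, -1), c(24.5, 24.5, 19), zp), g)
  b <- voxelize(box_roi("b", c(14.5, 4.5, -1), c(34.5, 24.5, 19), zp), g)
  ov <- overlap(a, b)
  expect_equal(ov$overlap_pct, 50, tolerance = 0.5)
  expect_equal(overlap(a, b)$overlap_ml, overlap(b, a)$overlap_ml)
  expect_lte(ov$overlap_ml, ov$recurrence_vol_ml)
  expect_equal(overlap(a, a)$overlap_pct, 100)
  disjoint <- voxelize(box_roi("d", c(30.5, 30.5, -1), c(38.5, 38.5, 19), zp),
                       g)
  expect_equal(overlap(a, disjoint)$overlap_pct, 0)
  empty <- voxel_mask(array(0, dim = grid_dim(g)), g$origin, g$spacing)
  expect_error(overlap(empty, a), "zero volume")
})

test_that("margin expansion follows the ball-dilation law", {
  g <- centered_grid(c(90L, 90L, 90L), c(1, 1, 1))
  ball <- voxelize(sphere_roi("b", c(0, 0, 0), 20, grid_planes(g),
                              n_vertices = 180), g)
  e10 <- expand_margin(ball, 10)
  v_true <- 4 / 3 * pi * 30^3 / 1000               # 113.10 ml
  expect_equal(mask_volume_ml(e10), v_true, tolerance = 0.02)
  # extensive and monotone
  expect_identical(expand_margin(ball, 0)$occupancy,
                   binarize_mask(ball)$occupancy)
  expect_true(all(e10$occupancy >= binarize_mask(ball)$occupancy))
  e20 <- expand_margin(ball, 20)
  expect_true(all(e20$occupancy >= e10$occupancy))
  # approximate semigroup: 10 + 10 vs one 20 mm step
  e1010 <- expand_margin(e10, 10)
  expect_equal(mask_volume_ml(e1010), mask_volume_ml(e20), tolerance = 0.02)
  expect_error(expand_margin(ball, -1), "non-negative")
})

test_that("anisotropic spacing is respected in physical mm", {
  g <- centered_grid(c(40L, 40L, 24L), c(2, 2, 4))
  # single-voxel seed at the center
  occ <- array(0, dim = c(40, 40, 24))
  occ[20, 20, 12] <- 1
  seed <- voxel_mask(occ, g$origin, g$spacing)
  e <- expand_margin(seed, 8)
  idx <- which(e$occupancy == 1, arr.ind = TRUE)
  ctr <- index_to_phys(g, idx - 1)
  seed_pos <- index_to_phys(g, matrix(c(19, 19, 11), 1))
  d <- sqrt(rowSums(sweep(ctr, 2, seed_pos[1, ])^2))
  expect_lte(max(d), 8 + 1e-6)                     # nothing beyond 8 mm
  # voxel count matches the anisotropic ball exactly (center-to-center law)
  expect_equal(nrow(idx), nrow(rtrecur:::ball_kernel_offsets(8, c(2, 2, 4))))
})

test_that("max extension recovers constructed distances and modes order", {
  g <- grid_geometry(c(80L, 60L, 30L), c(-59.25, -44.25, -43.5),
                     c(1.5, 1.5, 3))
  boost <- voxelize(sphere_roi("b", c(0, 0, 0), 20, grid_planes(g),
                               n_vertices = 180), g)
  expect_equal(max_extension(boost, boost, "3d"), 0)
  # lobe tip 30 mm beyond the boost surface, in-plane
  fx <- make_recurrence_fixture(20, 30, direction = c(1, 0, 0),
                                z_planes = grid_planes(g))
  rec <- voxelize(fx$recurrence_roi, g)
  expect_equal(max_extension(rec, boost, "3d"), 3.0, tolerance = 0.037)
  # oblique elongated recurrence: worst-axial-slice measurement cannot
  # exceed the full 3D extension
  g2 <- grid_geometry(c(60L, 40L, 40L), c(-44.25, -29.25, -58.5),
                      c(1.5, 1.5, 3))
  boost2 <- voxelize(sphere_roi("b", c(0, 0, 0), 15, grid_planes(g2)), g2)
  lobe <- sphere_roi("l", c(25, 0, 45), 8, grid_planes(g2))
  rec2m <- voxelize(lobe, g2)
  rec2 <- voxel_mask(pmax(rec2m$occupancy, boost2$occupancy),
                     g2$origin, g2$spacing)
  expect_lte(max_extension(rec2, boost2, "axial"),
             max_extension(rec2, boost2, "3d") + 1e-9)
  expect_error(max_extension(rec2, voxel_mask(array(0, grid_dim(g2)),
                                              g2$origin, g2$spacing)),
               "empty")
})

test_that("classification flags nested shells correctly", {
  g <- grid_geometry(c(80L, 64L, 30L), c(-59.25, -47.25, -43.5),
                     c(1.5, 1.5, 3))
  boost <- voxelize(sphere_roi("b", c(0, 0, 0), 20, grid_planes(g),
                               n_vertices = 180), g)
  # recurrence entirely inside the boost
  inner <- voxelize(sphere_roi("r", c(2, 1, 0), 12, grid_planes(g)), g)
  cl <- classify_location(inner, boost)
  expect_true(all(cl$member))
  expect_equal(cl$outfield_vol_ml, 0)
  expect_equal(cl$max_extension_cm, 0)
  # recurrence = boost expanded to exactly the +12 mm shell: inside +15
  # and +20 but not inside boost or +10 at the 0.95 threshold
  shell12 <- expand_margin(boost, 12)
  cl12 <- classify_location(shell12, boost)
  expect_identical(unname(cl12$member), c(FALSE, FALSE, TRUE, TRUE))
  # coverage is non-decreasing across nested shells
  expect_true(all(diff(cl12$coverage) >= -1e-12))
  # the lobe fixture's closed-form expectations are reproduced
  fx <- make_recurrence_fixture(20, 12, z_planes = grid_planes(g))
  rec <- voxelize(fx$recurrence_roi, g)
  cl2 <- classify_location(rec, boost)
  expect_identical(unname(cl2$member), unname(fx$expected$member))
  expect_equal(unname(cl2$coverage), unname(fx$expected$coverage),
               tolerance = 0.02)
  expect_equal(cl2$max_extension_cm, fx$expected$max_extension_cm,
               tolerance = 0.05)
  # direction-resolved extension points along the protrusion axis
  expect_gt(cl2$direction_extension_cm[["x+"]],
            max(cl2$direction_extension_cm[c("x-", "y+", "y-")]))
})
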