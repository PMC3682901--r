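test_that("phantom generation is bit-identical under a fixed seed", {
  spec <- phantom_spec(shape = c(32L, 32L, 16L), spacing = c(4, 4, 4),
                       body_semiaxes = c(55, 50, 30),
                       features = list(list(center = c(15, 5, 5), radius = 8,
                                            hu = 300)),
                       target_center = c(0, 0, 0), boost_radius = 12,
                       ptv_radius = 18, transform = rigid_transform(5, 2, 0),
                       seed = 7)
  d1 <- file.path(withr::local_tempdir(), "p1")
  d2 <- file.path(withr::local_tempdir(), "p2")
  make_phantom(spec, d1)
  make_phantom(spec, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
})

test_that("the follow-up scan differs from planning by the stated motion", {
  # landmark check: the bright feature sphere's intensity centroid must move
  # by exactly the ground-truth transform
  g_truth <- rigid_transform(9, -6, 3, 0, 0, 0, 0, 0, 40)
  pair <- registration_pair(g_truth)
  landmark_centroid <- function(vol, hu_min) {
    w <- pmax(as.vector(vol$voxels) - hu_min, 0)
    as.numeric(crossprod(voxel_centers(vol), w) / sum(w))
  }
  c_fixed <- landmark_centroid(pair$fixed, 500)   # the 600 HU sphere
  c_moving <- landmark_centroid(pair$moving, 500)
  expect_lt(max(abs(rt_apply(g_truth, c_fixed) - c_moving)), 1.0)
})

test_that("phantom files re-read into consistent volumes and structures", {
  cs <- standard_case()
  planning <- read_ct_series(cs$phantom$paths$planning_ct)
  expect_identical(dim(planning), cs$spec$shape)
  expect_equal(planning$voxels, cs$phantom$planning$voxels)
  structs <- read_rtstruct(cs$phantom$paths$rtstruct,
                           planning$frame_of_reference)
  expect_true(all(c("PTV", "Boost") %in% names(structs)))
  # sphere structure volume matches its closed form within 1%
  g <- grid_geometry(cs$spec$shape, cs$spec$origin, cs$spec$spacing)
  v_ptv <- mask_volume_ml(voxelize(structs$PTV, g))
  expect_equal(v_ptv, cs$phantom$expected$ptv_volume_ml, tolerance = 0.01)
  dose <- read_rtdose(cs$phantom$paths$dose_base)
  expect_equal(max(dose$voxels), 44.5, tolerance = 1e-2)
})

test_that("a feature outside the grid is rejected", {
  expect_error(
    phantom_spec(shape = c(16L, 16L, 8L), spacing = c(2, 2, 2),
                 features = list(list(center = c(100, 0, 0), radius = 5,
                                      hu = 100))),
    "outside the phantom grid")
})

test_that("recurrence fixtures carry correct closed-form metadata", {
  # no protrusion: fully contained
  fx0 <- make_recurrence_fixture(20, 0)
  expect_true(all(fx0$expected$member))
  expect_equal(fx0$expected$max_extension_cm, 0)
  expect_equal(fx0$expected$recurrence_vol_ml, 4 / 3 * pi * 20^3 / 1000)
  # 12 mm protrusion: membership starts at the +15 mm shell
  fx12 <- make_recurrence_fixture(20, 12)
  expect_identical(unname(fx12$expected$member), c(FALSE, TRUE, TRUE, TRUE))
  # the union volume is below the sum of the sphere volumes (they overlap)
  expect_lt(fx12$expected$recurrence_vol_ml,
            (4 / 3 * pi * (20^3 + 10^3)) / 1000)
  # out-of-plane protrusion direction is rejected
  expect_error(make_recurrence_fixture(20, 10, direction = c(0, 0, 1)),
               "axial-plane")
})

test_that("phantom spec files read back through the pipeline dialect", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "shape: [32, 32, 16]",
    "spacing: [4, 4, 4]",
    "body_semiaxes: [55, 50, 30]",
    "features:",
    "  - center: [15, 5, 5]",
    "    radius: 8",
    "    hu: 300",
    "target_center: [0, 0, 0]",
    "boost_radius: 12",
    "ptv_radius: 18",
    "transform: {tx: 5, ty: 2, rz: 20}",
    "seed: 3",
    "recurrence:",
    "  extension_mm: 10"), f)
  ps <- read_phantom_spec(f)
  expect_s3_class(ps$spec, "PhantomSpec")
  expect_equal(ps$spec$transform$rz, 20)
  expect_equal(ps$recurrence$expected$max_extension_cm, 1)
})
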