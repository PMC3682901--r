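make_ct <- function(dim = c(24L, 20L, 8L), spacing = c(2, 2.5, 3),
                    origin = c(-30, -25, -12), seed = 5) {
  set.seed(seed)
  vox <- array(round(stats::rnorm(prod(dim), -150, 180)), dim)
  image_volume(vox, origin, spacing,
               frame_of_reference = "2.25.900000000000000001")
}

test_that("CT series round-trips voxelwise and geometrically", {
  vol <- make_ct()
  d <- withr::local_tempdir()
  write_ct_series(vol, d)
  back <- read_ct_series(d)
  expect_identical(dim(back), dim(vol))
  expect_equal(back$voxels, vol$voxels)            # HU values exact
  expect_lt(max(abs(back$origin - vol$origin)), 1e-3)
  expect_lt(max(abs(back$spacing - vol$spacing)), 1e-6)
  expect_identical(back$frame_of_reference, vol$frame_of_reference)
})

test_that("slice order on disk does not affect the reconstructed volume", {
  vol <- make_ct(seed = 6)
  d <- withr::local_tempdir()
  paths <- write_ct_series(vol, d)
  shuffled <- file.path(d, "shuffled")
  dir.create(shuffled)
  set.seed(1)
  for (p in paths) # content decides position, never the file name
    file.rename(p, file.path(shuffled, sprintf("s%03d.dcm",
                                               sample.int(999L, 1L))))
  back <- read_ct_series(shuffled)
  expect_equal(back$voxels, vol$voxels)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
})

test_that("a missing slice is reported as irregular slice spacing", {
  vol <- make_ct()
  d <- withr::local_tempdir()
  paths <- write_ct_series(vol, d)
  file.remove(paths[4L])
  expect_error(read_ct_series(d), "irregular slice spacing")
})

test_that("structure sets round-trip vertices within 1e-3 mm", {
  frame <- "2.25.900000000000000002"
  r1 <- sphere_roi("Recurrence", c(5, -10, 0), 20, seq(-18, 18, 3), frame)
  r2 <- box_roi("Boost", c(-15, -15, -9), c(15, 15, 9), seq(-9, 9, 3), frame)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(list(r1, r2), f, frame)
  back <- read_rtstruct(f, frame)
  expect_named(back, c("Recurrence", "Boost"))
  expect_length(back$Recurrence$contours, length(r1$contours))
  worst <- max(mapply(function(a, b) max(abs(a - b)),
                      back$Recurrence$contours, r1$contours))
  expect_lt(worst, 1e-3)
  # circumradius of every sphere contour is bounded by the sphere radius
  for (ct in back$Recurrence$contours) {
    rad <- sqrt((ct[, 1] - 5)^2 + (ct[, 2] + 10)^2)
    expect_lte(max(rad), 20 + 1e-6)
  }
})

test_that("frame-of-reference mismatch warns and flags, never passes silently", {
  frame <- "2.25.900000000000000003"
  r <- sphere_roi("Recurrence", c(0, 0, 0), 10, c(-3, 0, 3), frame)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(list(r), f, frame)
  expect_warning(back <- read_rtstruct(f, "2.25.1"), "frame of reference")
  expect_true("frame_mismatch" %in% back$Recurrence$flags)
})

test_that("an ROI without contours reads back empty and flagged", {
  expect_error(roi("x", list(matrix(0, 2, 3))), "fewer than 3")
  r <- roi("Empty", list())
  expect_true("empty" %in% r$flags)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(list(r), f, "2.25.2")
  back <- read_rtstruct(f, "2.25.2")
  expect_length(back$Empty$contours, 0)
  expect_true("empty" %in% back$Empty$flags)
})

test_that("dose grids scale to absolute Gy and round-trip", {
  g <- centered_grid(c(16L, 16L, 8L), c(4, 4, 5))
  set.seed(7)
  dose <- image_volume(array(stats::runif(16 * 16 * 8, 0, 53.5),
                             c(16, 16, 8)), g$origin, g$spacing)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(dose, f)
  back <- read_rtdose(f)
  expect_lt(max(abs(back$voxels - dose$voxels)), 2e-3) # 16-bit quantization
  expect_identical(back$flags, character(0))
  # uniform prescription field stays exactly uniform
  uni <- image_volume(array(44.5, c(8, 8, 4)), c(0, 0, 0), c(5, 5, 5))
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(uni, f2)
  expect_equal(unique(as.vector(read_rtdose(f2)$voxels)), 44.5,
               tolerance = 1e-9)
})

test_that("a composite sum plan is flagged as non-analyzable per plan", {
  uni <- image_volume(array(53.5, c(8, 8, 4)), c(0, 0, 0), c(5, 5, 5))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(uni, f, summation_type = "MULTI_PLAN")
  back <- read_rtdose(f)
  expect_identical(back$flags, "sum_plan")
  expect_identical(back$summation_type, "MULTI_PLAN")
})

test_that("reports serialize identically to CSV and JSON with explicit nulls", {
  rep <- standard_report()
  d <- withr::local_tempdir()
  write_report(rep, file.path(d, "r.csv"), "csv")
  write_report(rep, file.path(d, "r.json"), "json")
  csv <- utils::read.csv(file.path(d, "r.csv"), check.names = FALSE)
  js <- jsonlite::read_json(file.path(d, "r.json"))
  for (col in c("base_recurrence_vol_ml", "base_median_gy",
                "boost_median_gy", "max_extension_cm"))
    expect_equal(csv[[col]], js[[col]], tolerance = 1e-9)
  expect_equal(csv$base_median_gy, round(rep$plans$base$stats$median_gy, 2))
})
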