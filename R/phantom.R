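# Synthetic CT/dose/structure phantoms with analytically known answers.
#
# Geometric phantoms (body ellipsoid in air, embedded contrast spheres)
# rendered with partial-volume supersampling -- edge voxels carry fractional
# intensities as real CT does -- plus analytic dose fields and sphere/box
# structures. The follow-up CT is the planning scene observed under a known
# rigid motion, so registration can be validated against ground truth. All
# outputs are written as genuine DICOM through the package's own writers.

#' Specification of a geometric phantom case
#'
#' Defaults describe the standard validation scene: an abdomen-sized body
#' ellipsoid with four embedded contrast spheres (vessel/organ surrogates),
#' a spherical target with a sequential base (44.5 Gy to the PTV) and boost
#' (9 Gy) plan, and a follow-up scan rotated and shifted by a known rigid
#' motion with mild Gaussian image noise.
#'
#' @param shape grid size (nx, ny, nz).
#' @param spacing voxel spacing mm; 3 mm slices as in clinical planning CT.
#' @param body_semiaxes,body_hu,air_hu body ellipsoid geometry and HU.
#' @param features list of contrast spheres: `list(center, radius, hu)`.
#' @param target_center,boost_radius,ptv_radius target geometry (mm).
#' @param plans named list of plans; each
#'   `list(prescribed_gy, fractions, plateau_radius, falloff_mm)` describes a
#'   spherical dose plateau at the prescription with linear falloff.
#' @param transform ground-truth [rigid_transform()] relating follow-up to
#'   planning frame (maps planning-frame points to follow-up coordinates).
#' @param noise_sd Gaussian HU noise (sd); makes the registration metric
#'   non-trivial.
#' @param shrink follow-up body-ellipsoid shrink factor (< 1 emulates the
#'   weight loss seen between planning and follow-up).
#' @param supersample partial-volume rendering factor per axis.
#' @param seed random seed; identical spec + seed gives bit-identical files.
#' @return An object of class `PhantomSpec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 40L),
                         spacing = c(2.5, 2.5, 3),
                         body_semiaxes = c(70, 60, 55),
                         body_hu = 0, air_hu = -1000,
                         features = list(
                           list(center = c(30, 10, 20), radius = 12, hu = 300),
                           list(center = c(-25, -20, -15), radius = 10,
                                hu = -400),
                           list(center = c(0, 35, -25), radius = 8, hu = 600),
                           list(center = c(-15, 25, 25), radius = 9,
                                hu = 150)),
                         target_center = c(10, 5, 0),
                         boost_radius = 20, ptv_radius = 30,
                         plans = list(
                           base = list(prescribed_gy = 44.5, fractions = 25L,
                                       plateau_radius = 35, falloff_mm = 25),
                           boost = list(prescribed_gy = 9, fractions = 5L,
                                        plateau_radius = 22,
                                        falloff_mm = 15)),
                         transform = rigid_transform(),
                         noise_sd = 10, shrink = 1, supersample = 2L,
                         seed = 0L) {
  shape <- as.integer(shape)
  origin <- -(shape - 1) / 2 * spacing   # grid centered on the isocenter
  extent_lo <- origin - spacing / 2
  extent_hi <- origin + (shape - 0.5) * spacing
  for (ft in features) {
    if (any(ft$center - ft$radius < extent_lo) ||
        any(ft$center + ft$radius > extent_hi))
      stop("feature sphere extends outside the phantom grid")
  }
  if (any(target_center - ptv_radius < extent_lo) ||
      any(target_center + ptv_radius > extent_hi))
    stop("target structure extends outside the phantom grid")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 body_semiaxes = body_semiaxes, body_hu = body_hu,
                 air_hu = air_hu, features = features,
                 target_center = target_center, boost_radius = boost_radius,
                 ptv_radius = ptv_radius, plans = plans,
                 transform = transform, noise_sd = noise_sd,
                 shrink = shrink, supersample = as.integer(supersample),
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# evaluate phantom HU at physical points (planning-frame content)
phantom_hu_at <- function(spec, x, shrink = 1) {
  hu <- rep(spec$air_hu, nrow(x))
  semi <- spec$body_semiaxes * shrink
  inside <- (x[, 1L] / semi[1L])^2 + (x[, 2L] / semi[2L])^2 +
    (x[, 3L] / semi[3L])^2 <= 1
  hu[inside] <- spec$body_hu
  for (ft in spec$features) {
    d2 <- (x[, 1L] - ft$center[1L])^2 + (x[, 2L] - ft$center[2L])^2 +
      (x[, 3L] - ft$center[3L])^2
    hu[d2 <= ft$radius^2] <- ft$hu
  }
  hu
}

# render a CT volume; `transform` maps planning-frame points to the rendered
# frame, so content is evaluated at its inverse (partial-volume supersampled)
render_phantom_ct <- function(spec, transform = NULL, shrink = 1,
                              frame_of_reference = "") {
  grid <- grid_geometry(spec$shape, spec$origin, spec$spacing)
  ss <- spec$supersample
  steps <- (seq_len(ss) - 0.5) / ss - 0.5
  offs <- as.matrix(expand.grid(ox = steps, oy = steps, oz = steps))
  y0 <- voxel_centers(grid)
  acc <- 0
  inv <- if (is.null(transform)) NULL else rt_invert(transform)
  for (i in seq_len(nrow(offs))) {
    y <- sweep(y0, 2L, offs[i, ] * spec$spacing, "+")
    x <- if (is.null(inv)) y else rt_apply(inv, y)
    acc <- acc + phantom_hu_at(spec, x, shrink)
  }
  hu <- acc / nrow(offs)
  if (spec$noise_sd > 0) hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sd)
  image_volume(array(round(hu), dim = spec$shape), spec$origin, spec$spacing,
               frame_of_reference = frame_of_reference)
}

# analytic spherical plateau-falloff dose field rendered on the grid
render_dose_field <- function(plan, center, grid, frame_of_reference = "") {
  x <- voxel_centers(grid)
  r <- sqrt((x[, 1L] - center[1L])^2 + (x[, 2L] - center[2L])^2 +
              (x[, 3L] - center[3L])^2)
  frac <- pmin(pmax(1 - (r - plan$plateau_radius) / plan$falloff_mm, 0), 1)
  image_volume(array(plan$prescribed_gy * frac, dim = grid_dim(grid)),
               grid$origin, grid$spacing,
               frame_of_reference = frame_of_reference)
}

#' Generate a complete phantom case on disk
#'
#' Renders the planning CT, the follow-up CT (planning scene under the
#' ground-truth rigid motion, with optional body shrinkage), the per-plan
#' dose grids and the structure set, writes everything as DICOM through the
#' package's writers, and attaches closed-form expected values
#' (structure volumes, plateau doses, the ground-truth transform) as
#' machine-readable metadata.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory.
#' @param recurrence optional recurrence fixture from
#'   [make_recurrence_fixture()]; its ROIs are added to the structure sets
#'   (the recurrence written in the follow-up frame, as delineated).
#' @return Invisibly, a list with the in-memory volumes, ROIs, file paths
#'   and `expected` metadata.
#' @export
make_phantom <- function(spec, dir, recurrence = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  frame_plan <- dcm_new_uid()
  frame_fu <- dcm_new_uid()
  planning <- render_phantom_ct(spec, frame_of_reference = frame_plan)
  followup <- render_phantom_ct(spec, transform = spec$transform,
                                shrink = spec$shrink,
                                frame_of_reference = frame_fu)
  grid <- grid_geometry(spec$shape, spec$origin, spec$spacing)
  z_planes <- spec$origin[3L] + (seq_len(spec$shape[3L]) - 1L) *
    spec$spacing[3L]
  ptv <- sphere_roi("PTV", spec$target_center, spec$ptv_radius, z_planes,
                    frame_plan)
  boost <- sphere_roi("Boost", spec$target_center, spec$boost_radius,
                      z_planes, frame_plan)
  rois <- list(ptv, boost)
  paths <- list(
    planning_ct = file.path(dir, "planning_ct"),
    followup_ct = file.path(dir, "followup_ct"),
    rtstruct = file.path(dir, "rtstruct.dcm"),
    transform = file.path(dir, "transform_ground_truth.txt"),
    expected = file.path(dir, "expected.json")
  )
  write_ct_series(planning, paths$planning_ct)
  write_ct_series(followup, paths$followup_ct)
  if (!is.null(recurrence)) {
    # the recurrence is delineated on the (unregistered) follow-up scan:
    # carry its planning-frame geometry into the follow-up frame and write
    # it as a separate structure set referencing that frame
    rec_fu <- transform_roi(recurrence$recurrence_roi, spec$transform)
    rec_fu$frame_of_reference <- frame_fu
    paths$rtstruct_followup <- file.path(dir, "rtstruct_followup.dcm")
    write_rtstruct(list(rec_fu), paths$rtstruct_followup, frame_fu)
    rois <- c(rois, list(rec_fu))
  }
  write_rtstruct(rois[1:2], paths$rtstruct, frame_plan)
  doses <- list()
  for (lab in names(spec$plans)) {
    plan <- spec$plans[[lab]]
    dv <- render_dose_field(plan, spec$target_center, grid, frame_plan)
    p <- file.path(dir, sprintf("dose_%s.dcm", lab))
    write_rtdose(dv, p)
    doses[[lab]] <- dv
    paths[[paste0("dose_", lab)]] <- p
  }
  write_transform(spec$transform, paths$transform)
  expected <- list(
    ptv_volume_ml = 4 / 3 * pi * spec$ptv_radius^3 / 1000,
    boost_volume_ml = 4 / 3 * pi * spec$boost_radius^3 / 1000,
    plateau_dose_gy = lapply(spec$plans, function(p) p$prescribed_gy),
    transform = unclass(spec$transform)
  )
  if (!is.null(recurrence)) expected$recurrence <- recurrence$expected
  jsonlite::write_json(expected, paths$expected, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(spec = spec, planning = planning, followup = followup,
                 rois = rois, doses = doses, paths = paths,
                 expected = expected,
                 frames = list(planning = frame_plan, followup = frame_fu)))
}

#' Read a phantom specification from YAML
#'
#' Same config dialect as the pipeline: top-level keys matching
#' [phantom_spec()] arguments (with `transform` given as the nine named
#' components), plus an optional `recurrence` block with
#' [make_recurrence_fixture()] arguments.
#'
#' @param path YAML file.
#' @return list with elements `spec` ([phantom_spec()]) and `recurrence`
#'   (fixture list or `NULL`).
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  rec_block <- x$recurrence
  x$recurrence <- NULL
  if (!is.null(x$transform))
    x$transform <- do.call(rigid_transform, x$transform)
  for (k in c("shape", "spacing", "body_semiaxes", "target_center"))
    if (!is.null(x[[k]])) x[[k]] <- as.numeric(unlist(x[[k]]))
  known <- names(formals(phantom_spec))
  spec <- do.call(phantom_spec, x[names(x) %in% known])
  recurrence <- NULL
  if (!is.null(rec_block)) {
    rec_block$z_planes <- spec$origin[3L] +
      (seq_len(spec$shape[3L]) - 1L) * spec$spacing[3L]
    if (is.null(rec_block$center)) rec_block$center <- spec$target_center
    if (is.null(rec_block$boost_radius_mm))
      rec_block$boost_radius_mm <- spec$boost_radius
    if (!is.null(rec_block$direction))
      rec_block$direction <- as.numeric(unlist(rec_block$direction))
    recurrence <- do.call(make_recurrence_fixture,
                          rec_block[names(rec_block) %in%
                                      names(formals(make_recurrence_fixture))])
  }
  list(spec = spec, recurrence = recurrence)
}

# ---- recurrence fixtures ----------------------------------------------------

# union outline of two circles on one plane; returns a list of contours
circle_union_contours <- function(c1, r1, c2, r2, z, n = 96L) {
  if (is.null(r1) && is.null(r2)) return(list())
  if (is.null(r2)) return(list(circle_contour(c1, r1, z, n)))
  if (is.null(r1)) return(list(circle_contour(c2, r2, z, n)))
  d <- sqrt(sum((c2 - c1)^2))
  if (d + r2 <= r1 + 1e-9) return(list(circle_contour(c1, r1, z, n)))
  if (d + r1 <= r2 + 1e-9) return(list(circle_contour(c2, r2, z, n)))
  if (d >= r1 + r2 - 1e-9)
    return(list(circle_contour(c1, r1, z, n), circle_contour(c2, r2, z, n)))
  alpha <- atan2(c2[2L] - c1[2L], c2[1L] - c1[1L])
  a1 <- acos((r1^2 + d^2 - r2^2) / (2 * r1 * d))
  a2 <- acos((r2^2 + d^2 - r1^2) / (2 * r2 * d))
  beta <- alpha + pi
  arc <- function(center, radius, from, to, m) {
    th <- seq(from, to, length.out = m)
    cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th), z)
  }
  m1 <- max(8L, round(n * (2 * pi - 2 * a1) / (2 * pi)))
  m2 <- max(8L, round(n * (2 * pi - 2 * a2) / (2 * pi)))
  # CCW: circle-1 arc outside circle 2, then circle-2 arc outside circle 1
  p1 <- arc(c1, r1, alpha + a1, alpha + 2 * pi - a1, m1)
  p2 <- arc(c2, r2, beta + a2 - 2 * pi, beta - a2, m2)
  list(rbind(p1, p2))
}

# volume of the lens-shaped intersection of two spheres
sphere_lens_volume <- function(R, r, d) {
  if (d >= R + r) return(0)
  if (d <= abs(R - r)) return(4 / 3 * pi * min(R, r)^3)
  pi * (R + r - d)^2 *
    (d^2 + 2 * d * r - 3 * r^2 + 2 * d * R + 6 * r * R - 3 * R^2) / (12 * d)
}

#' Boost + recurrence fixture with a known protrusion
#'
#' The recurrence is the boost sphere united with a lobe sphere protruding a
#' known distance beyond the boost surface along `direction` (per-slice
#' union contours, so even-odd rasterization sees a single outline).
#' Closed-form expected values -- union volume, coverage fraction inside
#' each margin-expanded shell, membership flags and the maximal extension --
#' are attached as metadata.
#'
#' @param boost_radius_mm boost sphere radius.
#' @param extension_mm protrusion of the lobe tip beyond the boost surface
#'   (>= 0).
#' @param direction unit in-plane direction of the protrusion (axial
#'   component must be 0 so contours remain planar).
#' @param center boost center (mm).
#' @param z_planes axial contour planes (mm).
#' @param lobe_radius_mm lobe sphere radius.
#' @param margins_mm shell margins for the expected classification.
#' @param containment_threshold coverage fraction defining "within".
#' @param frame_of_reference frame identifier for the ROIs.
#' @return list with `boost_roi`, `recurrence_roi`, `expected`.
#' @export
make_recurrence_fixture <- function(boost_radius_mm = 20, extension_mm = 0,
                                    direction = c(1, 0, 0),
                                    center = c(0, 0, 0),
                                    z_planes = seq(-43.5, 43.5, 3),
                                    lobe_radius_mm = 10,
                                    margins_mm = c(10, 15, 20),
                                    containment_threshold = 0.95,
                                    frame_of_reference = "") {
  if (extension_mm < 0) stop("`extension_mm` must be non-negative")
  if (abs(direction[3L]) > 1e-9)
    stop("protrusion direction must be axial-plane (z component 0)")
  direction <- direction / sqrt(sum(direction^2))
  boost_roi <- sphere_roi("Boost", center, boost_radius_mm, z_planes,
                          frame_of_reference)
  dc <- boost_radius_mm + extension_mm - lobe_radius_mm
  lobe_center <- center + direction * dc
  contours <- list()
  for (z in z_planes) {
    dz1 <- z - center[3L]; dz2 <- z - lobe_center[3L]
    r1 <- if (abs(dz1) < boost_radius_mm)
      sqrt(boost_radius_mm^2 - dz1^2) else NULL
    r2 <- if (extension_mm > 0 && abs(dz2) < lobe_radius_mm)
      sqrt(lobe_radius_mm^2 - dz2^2) else NULL
    contours <- c(contours,
                  circle_union_contours(center[1:2], r1, lobe_center[1:2],
                                        r2, z))
  }
  rec_roi <- roi("Recurrence", contours, frame_of_reference)
  v_boost <- 4 / 3 * pi * boost_radius_mm^3
  v_lobe <- 4 / 3 * pi * lobe_radius_mm^3
  v_union <- v_boost + v_lobe -
    sphere_lens_volume(boost_radius_mm, lobe_radius_mm, dc)
  coverage <- vapply(c(0, margins_mm), function(m) {
    shell_r <- boost_radius_mm + m
    v_inside <- v_boost +
      (sphere_lens_volume(shell_r, lobe_radius_mm, dc) -
         sphere_lens_volume(boost_radius_mm, lobe_radius_mm, dc))
    min(1, v_inside / v_union)
  }, numeric(1))
  names(coverage) <- c("boost", sprintf("boost+%gmm", margins_mm))
  expected <- list(
    recurrence_vol_ml = v_union / 1000,
    boost_vol_ml = v_boost / 1000,
    coverage = coverage,
    member = coverage >= containment_threshold,
    max_extension_cm = extension_mm / 10,
    margins_mm = margins_mm
  )
  list(boost_roi = boost_roi, recurrence_roi = rec_roi, expected = expected)
}
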