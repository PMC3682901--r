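# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except files the tests themselves write.

# centered axis-aligned grid
centered_grid <- function(dim, spacing) {
  grid_geometry(dim, -(dim - 1) / 2 * spacing, spacing)
}

# dose volume with a linear gradient `lo -> hi` along the z axis
gradient_dose <- function(dim = c(24L, 24L, 50L), spacing = c(4, 4, 2),
                          lo = 0, hi = 50) {
  g <- centered_grid(dim, spacing)
  z <- seq(lo, hi, length.out = dim[3L])
  image_volume(array(rep(z, each = dim[1L] * dim[2L]), dim),
               g$origin, g$spacing)
}

# axial plane positions of a grid
grid_planes <- function(grid) {
  d <- dim(grid$voxels)
  grid$origin[3L] + (seq_len(d[3L]) - 1L) * grid$spacing[3L]
}

# standard registration phantom pair with known ground truth
registration_pair <- function(ground_truth, noise_seed = 1) {
  spec <- phantom_spec(transform = ground_truth, seed = noise_seed)
  set.seed(spec$seed)
  fixed <- rtrecur:::render_phantom_ct(spec)
  moving <- rtrecur:::render_phantom_ct(spec, transform = ground_truth)
  list(spec = spec, fixed = fixed, moving = moving)
}

# maximum transform discrepancy: effective translation (mm) and angles (deg)
transform_errors <- function(a, b) {
  c(translation = max(abs(rt_effective_translation(a) -
                            rt_effective_translation(b))),
    angle = max(abs(rt_angles(a) - rt_angles(b))))
}

# one fully written phantom case (built once per test session)
.case_cache <- new.env(parent = emptyenv())
standard_case <- function() {
  if (!is.null(.case_cache$case)) return(.case_cache$case)
  dir <- file.path(tempdir(), "rtrecur-standard-case")
  g_truth <- rigid_transform(12, -8, 6, 0, 0, 0, 0, 0, 40)
  spec <- phantom_spec(transform = g_truth, seed = 1)
  fx <- make_recurrence_fixture(
    boost_radius_mm = spec$boost_radius, extension_mm = 12,
    center = spec$target_center,
    z_planes = spec$origin[3] + (seq_len(spec$shape[3]) - 1) * spec$spacing[3])
  ph <- make_phantom(spec, dir, recurrence = fx)
  cfg <- case_config(list(
    patient_id = "phantom-01",
    planning_ct = "planning_ct",
    followup_ct = "followup_ct",
    structures = list(planning = "rtstruct.dcm",
                      followup = "rtstruct_followup.dcm"),
    plans = list(
      list(label = "base", dose = "dose_base.dcm", fractions = 25,
           prescribed_gy = 44.5),
      list(label = "boost", dose = "dose_boost.dcm", fractions = 5,
           prescribed_gy = 9)),
    registration = list(hint_deg = 40, seed = 0)
  ), base_dir = dir)
  .case_cache$case <- list(dir = dir, ground_truth = g_truth, spec = spec,
                           fixture = fx, phantom = ph, config = cfg)
  .case_cache$case
}

# report of the standard case (computed once, reused by pipeline tests)
standard_report <- function() {
  if (is.null(.case_cache$report))
    .case_cache$report <- run_case(standard_case()$config)
  .case_cache$report
}
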