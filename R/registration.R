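# Rigid mutual-information registration of a follow-up CT to the planning CT.
#
# A transform maps points in the fixed (planning) frame to sampling locations
# in the moving (follow-up) frame: registration seeks T with
# moving(T(x)) ~ fixed(x). Follow-up acquisitions in oblique positioning can
# differ by large axial rotations, so an explicit pre-initialization step
# (centroid alignment plus an optional axial-angle hint) precedes the
# optimization.

#' Registration parameter set
#'
#' Conventional mutual-information settings, all configurable: histogram
#' bins, random sampling fraction of fixed-image foreground voxels, number
#' of multi-resolution pyramid levels, maximum optimizer iterations per
#' level, relative convergence tolerance, and the random seed recorded in
#' every result.
#'
#' @param bins joint-histogram bins per axis (>= 2).
#' @param sampling_fraction fraction of foreground voxels sampled, in (0, 1].
#' @param pyramid_levels multi-resolution levels (level 1 = full resolution).
#' @param max_iterations optimizer iteration cap per level.
#' @param tolerance relative convergence tolerance of the optimizer.
#' @param seed random seed for voxel sampling.
#' @return An object of class `RegistrationParams`.
#' @export
registration_params <- function(bins = 50L, sampling_fraction = 0.25,
                                pyramid_levels = 3L, max_iterations = 200L,
                                tolerance = 1e-9, seed = 0L) {
  stopifnot(bins >= 2L, sampling_fraction > 0, sampling_fraction <= 1,
            pyramid_levels >= 1L, max_iterations >= 1L, tolerance > 0)
  structure(list(bins = as.integer(bins),
                 sampling_fraction = sampling_fraction,
                 pyramid_levels = as.integer(pyramid_levels),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "RegistrationParams")
}

# intensity centroid with non-negative weights (shifted by the minimum)
intensity_centroid <- function(vol) {
  w <- as.vector(vol$voxels) - min(vol$voxels)
  total <- sum(w)
  if (total <= 0) stop("all-constant image: intensity centroid undefined")
  as.numeric(crossprod(voxel_centers(vol), w) / total)
}

#' Pre-initialize a registration
#'
#' Returns a deterministic starting transform that aligns the intensity
#' centroids of the two volumes and, when an axial-angle hint is given,
#' applies that rotation about the fixed volume's centroid. Heavily rotated
#' follow-up acquisitions (oblique patient positioning of 20-60 degrees)
#' are outside the capture range of the metric optimization alone, which is
#' why this step exists.
#'
#' @param fixed,moving [image_volume()] objects.
#' @param hint optional axial (z) rotation angle in degrees.
#' @return A [rigid_transform()] mapping fixed-frame points into the moving
#'   frame.
#' @export
preinitialize <- function(fixed, moving, hint = NULL) {
  cf <- intensity_centroid(fixed)
  cm <- intensity_centroid(moving)
  t <- cm - cf
  rz <- if (is.null(hint)) 0 else hint
  rigid_transform(tx = t[1L], ty = t[2L], tz = t[3L],
                  rpx = cf[1L], rpy = cf[2L], rpz = cf[3L],
                  rz = rz)
}

# block-mean downsample by integer factors (pyramid construction)
downsample_volume <- function(vol, factor) {
  if (all(factor == 1L)) return(vol)
  d <- dim(vol$voxels)
  nd <- pmax(d %/% factor, 1L)
  v <- vol$voxels[seq_len(nd[1L] * factor[1L]),
                  seq_len(nd[2L] * factor[2L]),
                  seq_len(nd[3L] * factor[3L]), drop = FALSE]
  a <- array(v, dim = c(factor[1L], nd[1L], factor[2L], nd[2L],
                        factor[3L], nd[3L]))
  m <- apply(a, c(2L, 4L, 6L), mean)
  # origin moves to the center of the first averaged block
  new_origin <- as.numeric(
    vol$origin + vol$orientation %*% ((factor - 1) / 2 * vol$spacing))
  image_volume(m, new_origin, vol$spacing * factor, vol$orientation,
               vol$frame_of_reference)
}

# negative mutual information of fixed samples vs moving values at T(points)
neg_mutual_information <- function(par, points, fvals, moving, bins,
                                   f_range, m_range, rp) {
  t <- rigid_transform(par[1L], par[2L], par[3L], rp[1L], rp[2L], rp[3L],
                       par[4L], par[5L], par[6L])
  mv <- interp_volume(moving, rt_apply(t, points), "linear", fill = NA_real_)
  keep <- !attr(mv, "outside")
  n <- sum(keep)
  if (n < length(fvals) * 0.1) return(0) # lost overlap: no information
  fi <- pmin(pmax(floor((fvals[keep] - f_range[1L]) /
                          (f_range[2L] - f_range[1L]) * bins) + 1L, 1L), bins)
  mi <- pmin(pmax(floor((mv[keep] - m_range[1L]) /
                          (m_range[2L] - m_range[1L]) * bins) + 1L, 1L), bins)
  joint <- tabulate(fi + bins * (mi - 1L), nbins = bins * bins) / n
  pf <- tabulate(fi, nbins = bins) / n
  pm <- tabulate(mi, nbins = bins) / n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  -(ent(pf) + ent(pm) - ent(joint))
}

#' Rigid mutual-information registration
#'
#' Multi-resolution (coarse-to-fine) maximization of the mutual information
#' between the fixed image and the resampled moving image over the six rigid
#' degrees of freedom, starting from `init` (usually [preinitialize()]).
#' The rotation point of `init` is kept fixed during optimization, so the
#' result is directly interpretable as translation + rotation about that
#' point. Voxel sampling is seeded: identical seeds give bit-identical
#' results.
#'
#' @param fixed,moving [image_volume()] objects.
#' @param init starting [rigid_transform()]; `NULL` for [preinitialize()].
#' @param params a [registration_params()].
#' @param mask optional [voxel_mask()] on the fixed grid restricting the
#'   sampled voxels (e.g. a dilated union of target and spinal-cord
#'   structures); default none.
#' @return An object of class `RegistrationResult`: fields `transform`,
#'   `metric` (final negative mutual information), `params`, `trace`.
#' @export
register_rigid <- function(fixed, moving, init = NULL,
                           params = registration_params(), mask = NULL) {
  if (is.null(init)) init <- preinitialize(fixed, moving)
  rp <- c(init$rpx, init$rpy, init$rpz)
  # overlap precondition: foreground of fixed must land in moving
  fg_thr <- min(fixed$voxels) + 0.05 * diff(range(fixed$voxels))
  fg_idx <- which(as.vector(fixed$voxels) > fg_thr)
  if (length(fg_idx) == 0L) stop("fixed image has no foreground")
  probe <- voxel_centers(fixed)[fg_idx[seq(1L, length(fg_idx),
                                           length.out = min(2000L,
                                                            length(fg_idx)))],
                               , drop = FALSE]
  pv <- interp_volume(moving, rt_apply(init, probe), "nearest")
  if (mean(!attr(pv, "outside")) < 0.10)
    stop("initialized volumes overlap by less than 10% of the fixed foreground")
  f_range <- range(fixed$voxels)
  m_range <- range(moving$voxels)
  par <- c(init$tx, init$ty, init$tz, init$rx, init$ry, init$rz)
  trace <- list()
  factors <- 2L^((params$pyramid_levels:1L) - 1L)
  for (li in seq_along(factors)) {
    f <- factors[li]
    fx <- downsample_volume(fixed, rep(f, 3L))
    mv <- downsample_volume(moving, rep(f, 3L))
    fvals_all <- as.vector(fx$voxels)
    cand <- which(fvals_all > fg_thr)
    if (!is.null(mask) && f == 1L) {
      keep_mask <- as.vector(mask$occupancy) >= 0.5
      cand2 <- intersect(cand, which(keep_mask))
      if (length(cand2) > 100L) cand <- cand2
    }
    # coarse levels carry few voxels: sample them fully and widen histogram
    # bins so the joint histogram stays populated
    frac_level <- if (f > 1L) 1 else params$sampling_fraction
    bins_level <- if (f > 1L) max(8L, params$bins %/% f) else params$bins
    n_take <- max(200L, round(length(cand) * frac_level))
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(params$seed + li)
    take <- if (n_take >= length(cand)) cand else sample(cand, n_take)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    points <- voxel_centers(fx)[take, , drop = FALSE]
    fvals <- fvals_all[take]
    start_val <- neg_mutual_information(par, points, fvals, mv, bins_level,
                                        f_range, m_range, rp)
    # Nelder-Mead with a simplex sized to the level (coarse levels explore,
    # the full-resolution level refines); restarting re-inflates a collapsed
    # simplex and guards against premature convergence.
    scale <- max(2, 4 * f)
    opt <- list(par = par, value = start_val)
    for (restart in 1:3) {
      opt_new <- stats::optim(opt$par, neg_mutual_information,
                              points = points, fvals = fvals, moving = mv,
                              bins = bins_level, f_range = f_range,
                              m_range = m_range, rp = rp,
                              method = "Nelder-Mead",
                              control = list(
                                maxit = params$max_iterations * 10L,
                                reltol = params$tolerance,
                                parscale = rep(scale, 6L)))
      improved <- opt_new$value < opt$value - 1e-10
      if (opt_new$value <= opt$value) opt <- opt_new
      if (!improved) break
      scale <- scale / 2
    }
    if (opt$value > start_val + 1e-12) {
      best <- rigid_transform(par[1L], par[2L], par[3L], rp[1L], rp[2L],
                              rp[3L], par[4L], par[5L], par[6L])
      cond <- simpleError(sprintf(
        "optimizer diverged at pyramid level %d (metric %.6f -> %.6f)",
        li, start_val, opt$value))
      cond$best_transform <- best
      stop(cond)
    }
    par <- opt$par
    trace[[li]] <- list(factor = f, metric = opt$value,
                        iterations = opt$counts[[1L]])
  }
  transform <- rigid_transform(par[1L], par[2L], par[3L], rp[1L], rp[2L],
                               rp[3L], par[4L], par[5L], par[6L])
  structure(list(transform = transform, metric = trace[[length(trace)]]$metric,
                 params = params, trace = trace),
            class = "RegistrationResult")
}

#' @export
print.RegistrationResult <- function(x, ...) {
  cat("<RegistrationResult>\n")
  print(x$transform)
  cat(sprintf("  final negative MI: %.6f (seed %d, %d level(s))\n",
              x$metric, x$params$seed, length(x$trace)))
  invisible(x)
}

#' Resample a volume through a rigid transform onto a target grid
#'
#' `out(x) = moving(T(x))` for every voxel center `x` of the target grid:
#' with `T` from [register_rigid()] this produces the registered follow-up
#' on the planning grid. Out-of-field voxels receive `fill` and their count
#' is reported in the `outside_count` field of the result.
#'
#' @param moving an [image_volume()].
#' @param transform a [rigid_transform()].
#' @param target_grid an [image_volume()] supplying the output geometry.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill value assigned outside the moving volume's field of view.
#' @return An [image_volume()] on the target grid with extra field
#'   `outside_count`.
#' @export
apply_transform <- function(moving, transform, target_grid,
                            interpolation = c("linear", "nearest"),
                            fill = NA_real_) {
  interpolation <- match.arg(interpolation)
  centers <- voxel_centers(target_grid)
  vals <- interp_volume(moving, rt_apply(transform, centers), interpolation,
                        fill = fill)
  out <- image_volume(array(as.numeric(vals), dim = grid_dim(target_grid)),
                      target_grid$origin, target_grid$spacing,
                      target_grid$orientation, target_grid$frame_of_reference)
  out$outside_count <- sum(attr(vals, "outside"))
  out
}

#' Transform an ROI point-wise
#'
#' Maps every contour vertex through `transform`; the contour count is
#' preserved. To carry a structure delineated on the follow-up frame into
#' the planning frame, pass the *inverse* of the registration transform
#' (which maps planning-frame points into the follow-up frame). A non-axial
#' rotation component tilts contours out of their axial planes; each
#' transformed contour is then flattened onto its mean plane with a warning
#' (axial patient rotations, the dominant mode in oblique acquisitions,
#' keep contours planar).
#'
#' @param roi an [roi()].
#' @param transform a [rigid_transform()].
#' @return The transformed `ROI`.
#' @export
transform_roi <- function(roi, transform) {
  warned <- FALSE
  contours <- lapply(roi$contours, function(ct) {
    v <- rt_apply(transform, ct)
    zr <- diff(range(v[, 3L]))
    if (zr > 1e-9) {
      # sub-millimetre tilt (residual rx/ry of an essentially axial motion)
      # is flattened silently; anything larger deserves a warning
      if (zr > 1 && !warned) {
        warning(sprintf(
          "contours tilted up to %.2f mm out of plane by non-axial %s",
          zr, "rotation; flattened to their mean planes"))
        warned <<- TRUE
      }
      v[, 3L] <- mean(v[, 3L])
    }
    v
  })
  roi(roi$name, contours, roi$frame_of_reference, roi$flags)
}
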