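#' Fractional-occupancy voxel mask
#'
#' Occupancy fractions in `[0, 1]` on a stated grid geometry, produced by
#' rasterizing planar contours on a subvoxel grid. `level` records the
#' supersampling exponent actually achieved (subgrid factor `2^level` per
#' in-plane axis).
#'
#' @param occupancy 3D array of fractions in `[0, 1]`.
#' @param origin,spacing,orientation grid geometry as in [image_volume()].
#' @param level achieved supersampling exponent.
#' @return An object of class `VoxelMask`.
#' @export
voxel_mask <- function(occupancy, origin, spacing, orientation = diag(3),
                       level = 0L) {
  if (length(dim(occupancy)) != 3L) stop("`occupancy` must be a 3D array")
  rng <- range(occupancy)
  if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9)
    stop("occupancy fractions must lie in [0, 1]")
  structure(list(occupancy = pmin(pmax(occupancy, 0), 1),
                 origin = as.numeric(origin), spacing = as.numeric(spacing),
                 orientation = matrix(as.numeric(orientation), 3L, 3L),
                 level = as.integer(level)),
            class = "VoxelMask")
}

#' @export
print.VoxelMask <- function(x, ...) {
  cat(sprintf("<VoxelMask> %s voxels, volume %.2f ml, level %d (factor %d)\n",
              paste(dim(x$occupancy), collapse = " x "),
              mask_volume_ml(x), x$level, 2L^x$level))
  invisible(x)
}

#' Total mask volume in ml
#' @param mask a `VoxelMask`.
#' @export
mask_volume_ml <- function(mask) sum(mask$occupancy) * voxel_volume_ml(mask)

#' Binarize a fractional mask at 0.5 occupancy
#' @param mask a `VoxelMask`.
#' @export
binarize_mask <- function(mask) {
  voxel_mask((mask$occupancy >= 0.5) * 1, mask$origin, mask$spacing,
             mask$orientation, mask$level)
}

#' Bare grid geometry descriptor
#'
#' A voxel-grid geometry without meaningful intensities, usable wherever an
#' [image_volume()] supplies only its geometry (e.g. as the `grid` argument
#' of [voxelize()]).
#'
#' @param dim grid size (nx, ny, nz).
#' @param origin,spacing,orientation geometry as in [image_volume()].
#' @export
grid_geometry <- function(dim, origin, spacing, orientation = diag(3)) {
  list(voxels = array(0, dim = dim), origin = as.numeric(origin),
       spacing = as.numeric(spacing),
       orientation = matrix(as.numeric(orientation), 3L, 3L))
}

# non-adjacent edge pair intersection check (warns about self-intersection)
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n > 200L) return(FALSE) # O(n^2) guard; large contours assumed clean
  x <- v[, 1L]; y <- v[, 2L]
  nxt <- c(seq_len(n)[-1L], 1L)
  seg_int <- function(a, b, c, d) {
    d1 <- (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
    d2 <- (b[1L] - a[1L]) * (d[2L] - a[2L]) - (b[2L] - a[2L]) * (d[1L] - a[1L])
    d3 <- (d[1L] - c[1L]) * (a[2L] - c[2L]) - (d[2L] - c[2L]) * (a[1L] - c[1L])
    d4 <- (d[1L] - c[1L]) * (b[2L] - c[2L]) - (d[2L] - c[2L]) * (b[1L] - c[1L])
    # a cross product of edge length L and point distance t is ~ L * t:
    # snap |cross| below L * 1e-7 mm to zero so shared vertices at fp
    # precision never register as crossings
    snap <- function(v, s) if (abs(v) < 1e-7 * s) 0 else v
    s1 <- sum(abs(b - a)); s2 <- sum(abs(d - c))
    snap(d1, s1) * snap(d2, s1) < 0 && snap(d3, s2) * snap(d4, s2) < 0
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next # adjacent through closure
      if (seg_int(c(x[i], y[i]), c(x[nxt[i]], y[nxt[i]]),
                  c(x[j], y[j]), c(x[nxt[j]], y[nxt[j]])))
        return(TRUE)
    }
  }
  FALSE
}

# Even-odd scanline rasterization of one or more polygons into fractional
# per-cell coverage on an (nx, ny) in-plane grid with supersampling factor f.
# x0/y0: physical position of the center of cell (0, 0); dx/dy: spacing.
rasterize_slice <- function(polys, nx, ny, x0, y0, dx, dy, f) {
  cov <- matrix(0, nx, ny)
  if (length(polys) == 0L) return(cov)
  edges <- do.call(rbind, lapply(polys, function(v) {
    n <- nrow(v)
    cbind(v[, 1L], v[, 2L], v[c(2:n, 1L), 1L], v[c(2:n, 1L), 2L])
  }))
  keep <- edges[, 2L] != edges[, 4L]
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L) return(cov)
  dxs <- dx / f
  xs0 <- x0 - dx / 2 + dxs / 2 # center of subcolumn m = 0
  n_sub_x <- nx * f
  e_y1 <- edges[, 2L]; e_y2 <- edges[, 4L]
  e_x1 <- edges[, 1L]; e_slope <- (edges[, 3L] - edges[, 1L]) / (e_y2 - e_y1)
  counts_cols <- integer(nx)
  for (j in seq_len(ny)) {
    acc <- numeric(nx)
    for (t in seq_len(f)) {
      yv <- y0 + (j - 1) * dy - dy / 2 + (t - 0.5) * dy / f
      hit <- (e_y1 <= yv) != (e_y2 <= yv)
      if (!any(hit)) next
      cr <- sort(e_x1[hit] + (yv - e_y1[hit]) * e_slope[hit])
      np <- length(cr) %/% 2L
      if (np == 0L) next
      cnt <- counts_cols
      for (p in seq_len(np)) {
        a <- cr[2L * p - 1L]; b <- cr[2L * p]
        m_lo <- ceiling((a - xs0) / dxs - 1e-12)
        m_hi <- floor((b - xs0) / dxs + 1e-12)
        if (m_hi < 0L || m_lo > n_sub_x - 1L || m_hi < m_lo) next
        m_lo <- max(m_lo, 0L); m_hi <- min(m_hi, n_sub_x - 1L)
        c_lo <- m_lo %/% f; c_hi <- m_hi %/% f
        if (c_lo == c_hi) {
          cnt[c_lo + 1L] <- cnt[c_lo + 1L] + (m_hi - m_lo + 1L)
        } else {
          cnt[c_lo + 1L] <- cnt[c_lo + 1L] + (c_lo * f + f - m_lo)
          cnt[c_hi + 1L] <- cnt[c_hi + 1L] + (m_hi - c_hi * f + 1L)
          if (c_hi > c_lo + 1L)
            cnt[(c_lo + 2L):c_hi] <- cnt[(c_lo + 2L):c_hi] + f
        }
      }
      acc <- acc + cnt
    }
    cov[, j] <- acc / (f * f)
  }
  cov
}

#' Voxelize an ROI onto a grid with subvoxel accuracy
#'
#' Per axial slice, the contour polygons are rasterized by the even-odd rule
#' on an in-plane subgrid of factor `2^level`; fractional occupancy is the
#' covered subcell fraction. Levels are increased until the total volume
#' changes by less than `tolerance` (relative) between consecutive levels, or
#' `max_level` is reached. The achieved level is recorded on the mask.
#'
#' @param roi an [roi()] object (vertices in physical mm).
#' @param grid grid geometry: an [image_volume()] (only geometry used) or the
#'   result of an internal geometry descriptor. Must be axis-aligned
#'   (identity orientation).
#' @param max_level maximum supersampling exponent (factor `2^max_level`).
#' @param tolerance relative volume-change convergence tolerance between
#'   consecutive levels.
#' @param level force a single supersampling exponent (disables the
#'   convergence loop); mainly for refinement studies.
#' @return A [voxel_mask()].
#' @export
voxelize <- function(roi, grid, max_level = 3L, tolerance = 0.005,
                     level = NULL) {
  if (length(roi$contours) == 0L) stop("cannot voxelize an empty ROI")
  if (max(abs(grid$orientation - diag(3))) > 1e-6)
    stop("voxelize requires an axis-aligned grid")
  d <- grid_dim(grid)
  dz <- grid$spacing[3L]
  for (ct in roi$contours)
    if (polygon_self_intersects(ct))
      warning("self-intersecting contour in '", roi$name,
              "' processed by even-odd rule")
  # group contours by grid slice
  slice_polys <- vector("list", d[3L])
  for (ct in roi$contours) {
    z <- ct[1L, 3L]
    k <- min(max(round((z - grid$origin[3L]) / dz), 0), d[3L] - 1)
    if (abs(z - (grid$origin[3L] + k * dz)) > dz / 2 + 1e-9)
      warning(sprintf(
        "contour plane z = %.3f mm matches no grid slice; assigned to nearest",
        z))
    slice_polys[[k + 1L]] <- c(slice_polys[[k + 1L]], list(ct[, 1:2,
                                                              drop = FALSE]))
  }
  levels <- if (is.null(level)) 0:max_level else as.integer(level)
  prev_vol <- NA_real_
  occ <- NULL; achieved <- levels[1L]
  for (lv in levels) {
    f <- 2L^lv
    occ_lv <- array(0, dim = d)
    for (k in seq_len(d[3L])) {
      if (is.null(slice_polys[[k]])) next
      occ_lv[, , k] <- rasterize_slice(
        slice_polys[[k]], d[1L], d[2L],
        grid$origin[1L], grid$origin[2L],
        grid$spacing[1L], grid$spacing[2L], f)
    }
    occ <- occ_lv; achieved <- lv
    vol <- sum(occ) * prod(grid$spacing) / 1000
    if (!is.na(prev_vol) && vol > 0 &&
        abs(vol - prev_vol) / vol < tolerance) break
    prev_vol <- vol
  }
  voxel_mask(occ, grid$origin, grid$spacing, grid$orientation, achieved)
}
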